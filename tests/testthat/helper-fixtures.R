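# Shared fixtures: everything is generated in code at test time.

# Minimal architecture that accepts 8^3 inputs and exposes a 4^3 x 2 feature
# grid (stem stride 2, no pool, one identity block).
tiny_arch <- function(channels = 2L) {
  architecture_spec(stem_channels = channels, stem_kernel = 3L,
                    stem_stride = 2L, stem_pool = FALSE,
                    stages = list(c(1L, channels)), dropout = 0)
}

tiny_model <- function(seed = 1, channels = 2L) {
  set.seed(seed)
  build_model(tiny_arch(channels))
}

# Hand-built probabilistic atlas from an explicit probability stack.
manual_atlas <- function(probs, lobe = NULL, hemisphere = NULL,
                         networks = NULL) {
  n <- dim(probs)[4]
  labels <- data.frame(
    index = seq_len(n) - 1L,
    name = sprintf("area%02d", seq_len(n)),
    hemisphere = if (is.null(hemisphere)) rep("L", n) else hemisphere,
    lobe = if (is.null(lobe)) sprintf("lobe%d", seq_len(n)) else lobe,
    networks = if (is.null(networks)) rep("net1", n) else networks,
    stringsAsFactors = FALSE)
  structure(list(grid_shape = dim(probs)[1:3], probs = probs,
                 labels = labels),
            class = "voxsal_atlas")
}

# Correlation table from explicit tau and p matrices.
manual_cortab <- function(tau, pvals, n = 20L) {
  diag(tau) <- 1
  diag(pvals) <- 0
  structure(list(tau = tau, pvals = pvals, n_subjects = n),
            class = "voxsal_cortab")
}

# Subject table with predictions equal to truth unless stated.
fake_subjects <- function(true_class, predicted = true_class,
                          fold = rep(1L, length(true_class))) {
  n <- length(true_class)
  data.frame(id = sprintf("S%03d", seq_len(n)), true_class = true_class,
             updrs_p3 = NA_real_, moca = NA_real_, ledd = NA_real_,
             years_onset = NA_real_, handedness = "R",
             medicated = FALSE, latent_severity = 0,
             fold = fold, predicted_class = predicted,
             stringsAsFactors = FALSE)
}
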