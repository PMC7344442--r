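# shared fixtures, all built in code

# small scenario for fast end-to-end runs
small_spec <- function(seed = 1L)
  scenario_spec(grid_shape = c(60, 60), seed = seed)

# a tiny raster with known composition
tiny_raster <- function(codes, nr = 4, nc = 4, cell_area = 1)
  land_raster(matrix(codes, nr, nc), cell_area = cell_area)

# all-allowed rules over codes 1..k
all_allowed_rules <- function(k = 7) {
  m <- matrix(1, k, k, dimnames = list(as.character(1:k), as.character(1:k)))
  transition_rules(m)
}

# a uniform suitability stack over codes for a given grid
uniform_suitability <- function(codes, nr, nc) {
  p <- lapply(codes, function(j) matrix(1 / length(codes), nr, nc))
  names(p) <- as.character(codes)
  structure(list(p = p, classes = as.integer(codes)),
            class = "suitability_stack")
}

# linearly separable two-class training fixture
separable_training <- function(n = 200, seed = 42) {
  set.seed(seed)
  x <- cbind(a = stats::runif(n), b = stats::runif(n))
  y <- ifelse(x[, 1] + x[, 2] > 1, 1L, 2L)
  structure(list(x = x, y = y, cells = seq_len(n),
                 layer_names = colnames(x)),
            class = "training_set")
}

# brute-force AUC: mean over all positive-negative pairs (ties half)
auc_bruteforce <- function(score, label) {
  pos <- score[as.logical(label)]
  neg <- score[!as.logical(label)]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# brute-force kappa from explicit marginal sums
kappa_bruteforce <- function(counts) {
  N <- sum(counts)
  po <- sum(diag(counts)) / N
  pe <- 0
  for (i in seq_len(nrow(counts)))
    pe <- pe + sum(counts[i, ]) * sum(counts[, i]) / N^2
  (po - pe) / (1 - pe)
}
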