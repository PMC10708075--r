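# Shared builders and independent oracles for the test suite.

toy_peak_table <- function() {
  areas <- rbind(c(2, 3, 5),
                 c(1, 1, 2),
                 c(4, 6, 10),
                 c(10, 0, 10))
  colnames(areas) <- c("cmp-a", "cmp-b", "cmp-c")
  peak_table(areas, groups = c("g1", "g1", "g2", "g2"))
}

toy_profile <- function(compound, mean_content, group = "g",
                        sd_content = 0, n = 4) {
  flavoromics:::new_group_profile(compound, mean_content,
                                  rep(sd_content, length(compound)),
                                  n, group, closure_tol = Inf)
}

toy_thresholds <- function(compound, threshold, descriptors = NULL) {
  threshold_table(compound, threshold, descriptors)
}

# first-principles ROAV: loop over compounds, OAV = C/T, scale by the max
roav_oracle <- function(contents, thresholds) {
  oav <- numeric(length(contents))
  for (i in seq_along(contents)) oav[i] <- contents[i] / thresholds[i]
  out <- numeric(length(oav))
  for (i in seq_along(oav)) out[i] <- 100 * oav[i] / max(oav)
  out
}

# direct-summation VIP over the model's weight vectors and SSY weights
vip_oracle <- function(model, type = "total") {
  W <- matrix(model$w, ncol = 1)
  ssy <- model$ssy_pred
  if (type == "total" && model$n_ortho > 0) {
    W <- cbind(W, model$W_o)
    ssy <- c(ssy, model$ssy_ortho)
  }
  p <- length(model$w)
  vip <- numeric(p)
  for (j in seq_len(p)) {
    num <- 0
    for (a in seq_along(ssy)) {
      wa <- W[, a] / sqrt(sum(W[, a]^2))
      num <- num + ssy[a] * wa[j]^2
    }
    vip[j] <- sqrt(p * num / sum(ssy))
  }
  vip
}

# two clearly separated gaussian clusters for discriminant tests
separable_data <- function(n_per = 4, p = 6, delta = 6, sd = 0.1,
                           seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(stats::rnorm(n_per * p, 0, sd), n_per, p),
             matrix(stats::rnorm(n_per * p, delta, sd), n_per, p))
  colnames(X) <- paste0("v", seq_len(p))
  list(X = X, y = rep(c("a", "b"), each = n_per))
}
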