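# Fixture builders and independent brute-force oracles used across tests.

random_count_table <- function(n_samples = 6, n_otus = 20, seed = 1,
                               lambda = 8) {
  set.seed(seed)
  m <- matrix(rpois(n_samples * n_otus, lambda), n_samples, n_otus,
              dimnames = list(sprintf("s%02d", seq_len(n_samples)),
                              sprintf("otu%03d", seq_len(n_otus))))
  m[rowSums(m) == 0, 1] <- 1L
  count_table(m)
}

random_meta <- function(n_oral = 4, n_faecal = 4, n_paired = 2, seed = 1) {
  set.seed(seed)
  n_ind <- n_oral + n_faecal - n_paired
  ind <- sprintf("I%02d", seq_len(n_ind))
  paired <- ind[seq_len(n_paired)]
  oral <- c(paired, ind[n_paired + seq_len(n_oral - n_paired)])
  faecal <- c(paired, setdiff(ind, oral))
  meta <- rbind(
    data.frame(individual_id = oral, region = "oral"),
    data.frame(individual_id = faecal, region = "faecal"))
  meta$sample_id <- paste0(substr(meta$region, 1, 1), "_", meta$individual_id)
  meta$sex <- rep_len(c("M", "F"), nrow(meta))
  meta[, c("sample_id", "individual_id", "region", "sex")]
}

# naive per-branch UniFrac via tip-descendant sets (independent of the
# package's incidence-matrix implementation)
unifrac_naive <- function(tree, x, y, weighted = FALSE, normalized = TRUE) {
  desc <- phangorn::Descendants(tree, tree$edge[, 2], type = "tips")
  tips <- tree$tip.label
  el <- tree$edge.length
  if (weighted) {
    px <- vapply(desc, function(tt) sum(x[tips[tt]]) / sum(x), 0)
    py <- vapply(desc, function(tt) sum(y[tips[tt]]) / sum(y), 0)
    raw <- sum(el * abs(px - py))
    if (!normalized) return(raw)
    # root-to-tip distance per leaf = sum of lengths of edges containing it
    dleaf <- vapply(seq_along(tips), function(i)
      sum(el[vapply(desc, function(tt) i %in% tt, TRUE)]), 0)
    names(dleaf) <- tips
    raw / sum(dleaf * (x[tips] / sum(x) + y[tips] / sum(y)))
  } else {
    inx <- vapply(desc, function(tt) any(x[tips[tt]] > 0), TRUE)
    iny <- vapply(desc, function(tt) any(y[tips[tt]] > 0), TRUE)
    sum(el[xor(inx, iny)]) / sum(el[inx | iny])
  }
}

# dense-matrix ML log-likelihood of the random-intercept model at a fixed
# variance pair; used by the grid-search oracle
lmm_loglik_at <- function(y, X, ind, s2_ind, s2_res) {
  Z <- outer(ind, unique(ind), `==`) * 1
  V <- s2_res * diag(length(y)) + s2_ind * tcrossprod(Z)
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  as.numeric(-0.5 * (determinant(V)$modulus + t(r) %*% Vi %*% r +
                       length(y) * log(2 * pi)))
}

# two-stage grid search over (s2_ind, s2_res); returns minimised deviance
lmm_griddev_oracle <- function(y, X, ind) {
  best <- c(NA, NA, Inf)
  s2r0 <- var(y)
  grid1 <- expand.grid(si = s2r0 * c(1e-6, seq(0.01, 2, length.out = 25)),
                       sr = s2r0 * seq(0.05, 2, length.out = 25))
  for (i in seq_len(nrow(grid1))) {
    d <- -2 * lmm_loglik_at(y, X, ind, grid1$si[i], grid1$sr[i])
    if (d < best[3]) best <- c(grid1$si[i], grid1$sr[i], d)
  }
  for (round in 1:7) {
    h <- 0.6 * 0.5^(round - 1)
    wsi <- max(best[1], s2r0 * 1e-3)
    si <- seq(max(0, best[1] - h * wsi), best[1] + h * wsi, length.out = 21)
    sr <- seq(best[2] * (1 - h), best[2] * (1 + h), length.out = 21)
    for (a in si) for (b in sr) {
      d <- -2 * lmm_loglik_at(y, X, ind, a, b)
      if (d < best[3]) best <- c(a, b, d)
    }
  }
  best[3]
}

expect_close <- function(object, expected, tol = 1e-10) {
  expect_equal(object, expected, tolerance = tol)
}
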