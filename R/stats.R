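#' Exact Mann-Whitney U test (two-sided)
#'
#' Rank-sum U with midranks for ties. The two-sided p value doubles the
#' smaller tail (capped at 1). For n1*n2 <= `exact_limit` the null
#' distribution of U is enumerated exactly over the permutation distribution
#' of the observed value multiset (dynamic programming over tie groups, which
#' is equivalent to full enumeration of all choose(n1+n2, n1) labelings);
#' otherwise a normal approximation with tie and continuity corrections is
#' used.
#'
#' @param a,b Numeric vectors (each non-empty, finite), e.g. percentage canal
#'   occupancy per specimen for two modalities.
#' @param exact_limit Largest n1*n2 for which the exact method is used
#'   (default 400).
#' @return Object of class `mw_test_result`: list with `U` (first sample),
#'   `p_two_sided`, `method` ("exact" or "normal-approx"), `n1`, `n2`.
#' @export
mann_whitney_exact <- function(a, b, exact_limit = 400L) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stopf("mann_whitney_exact: empty group")
  if (!all(is.finite(c(a, b)))) stopf("mann_whitney_exact: non-finite values")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b), ties.method = "average")
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2

  if (n1 * n2 <= exact_limit) {
    # Distribution of 2*R1 (midranks are multiples of 1/2) by polynomial DP
    # over tie groups: exact counts as doubles (< 2^53 for N <= 40).
    r2 <- as.integer(round(2 * r))
    groups <- table(r2)
    vals <- as.integer(names(groups))
    cnts <- as.integer(groups)
    maxs <- sum(sort(r2, decreasing = TRUE)[seq_len(n1)])
    # dp[k+1, s+1] = number of ways to pick k values summing (in 2R units) to s
    dp <- matrix(0, n1 + 1L, maxs + 1L)
    dp[1L, 1L] <- 1
    for (g in seq_along(vals)) {
      val <- vals[g]; cnt <- cnts[g]
      ndp <- matrix(0, n1 + 1L, maxs + 1L)
      for (j in 0:min(cnt, n1)) {
        w <- choose(cnt, j)
        if (j == 0) { ndp <- ndp + dp; next }
        ks <- (j + 1L):(n1 + 1L)
        shift <- j * val
        src_s <- seq_len(maxs + 1L - shift)
        ndp[ks, src_s + shift] <- ndp[ks, src_s + shift] +
          w * dp[ks - j, src_s, drop = FALSE]
      }
      dp <- ndp
    }
    counts <- dp[n1 + 1L, ]
    total <- choose(N, n1)
    u2 <- seq(0L, maxs) - n1 * (n1 + 1L)  # 2*U grid
    obs2 <- as.integer(round(2 * U))
    p_lo <- sum(counts[u2 <= obs2]) / total
    p_hi <- sum(counts[u2 >= obs2]) / total
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    s2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(s2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal-approx"
  }
  structure(list(U = U, p_two_sided = p, method = method, n1 = n1, n2 = n2),
            class = "mw_test_result")
}

#' @export
print.mw_test_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n1 = %d, n2 = %d), two-sided p = %.4g [%s]\n",
              x$U, x$n1, x$n2, x$p_two_sided, x$method))
  invisible(x)
}

#' Aggregate morphometric indices across datasets
#'
#' Arithmetic mean and sample SD (n-1 denominator) per parameter. For a
#' single dataset the SD is reported as 0 with a caveat message.
#'
#' @param indices A list of `morphometry_indices`.
#' @return data.frame with columns `parameter`, `mean`, `sd`, `n`.
#' @export
summarize_indices <- function(indices) {
  if (inherits(indices, "morphometry_indices")) indices <- list(indices)
  if (!length(indices)) stopf("summarize_indices: empty list")
  stopifnot(all(vapply(indices, inherits, logical(1), "morphometry_indices")))
  df <- do.call(rbind, lapply(indices, as.data.frame))
  pars <- c(canal_volume_pct = "Canal Volume (%)",
            canal_diameter_um = "Canal Diameter (microns)",
            canal_occupancy_pct = "Canal Occupancy (%)",
            vascular_space_pct = "Vascular Space (%)",
            lacunar_density_per_mm3 = "Number of Osteocyte Lacunae (# per mm3)")
  n <- nrow(df)
  if (n == 1L)
    message("summarize_indices: single dataset; SD reported as 0")
  out <- data.frame(
    parameter = unname(pars),
    mean = vapply(names(pars), function(k) mean(df[[k]]), numeric(1)),
    sd = vapply(names(pars), function(k) if (n > 1L) sd(df[[k]]) else 0,
                numeric(1)),
    n = n,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
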