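# internal helpers shared across modules

# expand one user seed into named child seeds so pipeline components can be
# re-run independently with identical randomness; all seeds stay < 2^31
.childSeeds <- function(seed, labels) {
  set.seed(as.integer(seed))
  s <- sample.int(.Machine$integer.max - 1L, length(labels))
  names(s) <- labels
  s
}

.logRowSumExp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Runs the Kruskal-Wallis rank-sum test across groups and, for the
#' omnibus-significant case (or always, when `always_posthoc`), Dunn's
#' z-tests on all group pairs with Benjamini-Hochberg adjustment. Dunn's
#' statistic uses the tie-corrected large-sample variance of mean ranks.
#'
#' @param values numeric response vector.
#' @param groups group labels (coerced to factor).
#' @param p_adjust_method adjustment for the pairwise p-values
#'   (default `"BH"`).
#' @param always_posthoc run the pairwise tests regardless of the omnibus
#'   p-value (default TRUE).
#' @return list with `h` (KW statistic), `p` (omnibus p), `posthoc`
#'   data.frame (group1, group2, z, p, p_adj).
#' @export
kruskalDunn <- function(values, groups, p_adjust_method = "BH",
                        always_posthoc = TRUE) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  kw <- stats::kruskal.test(values, groups)
  posthoc <- NULL
  if (always_posthoc || kw$p.value < 0.05) {
    r <- rank(values)
    n <- length(values)
    ties <- table(values)
    tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
    mr <- tapply(r, groups, mean)
    ng <- tapply(r, groups, length)
    lev <- levels(groups)
    pairs <- utils::combn(lev, 2L)
    z <- apply(pairs, 2L, function(pr) {
      se <- sqrt((n * (n + 1) / 12 - tie_corr) *
                   (1 / ng[[pr[1L]]] + 1 / ng[[pr[2L]]]))
      (mr[[pr[1L]]] - mr[[pr[2L]]]) / se
    })
    p <- 2 * stats::pnorm(-abs(z))
    posthoc <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                          z = z, p = p,
                          p_adj = stats::p.adjust(p, p_adjust_method),
                          row.names = NULL)
  }
  list(h = unname(kw$statistic), p = kw$p.value, posthoc = posthoc)
}
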