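# fixture builders shared across test files; everything is generated in
# code so the repository stays text-only

tinyTable <- function() {
  m <- matrix(c(10, 0, 5, 5, 0, 7), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("s", 1:3), c("t1", "t2")))
  featureTable(m)
}

randomTable <- function(n_samples, n_taxa, depth = 500, seed = 1) {
  set.seed(seed)
  p <- prop.table(stats::rlnorm(n_taxa, 0, 1))
  m <- t(stats::rmultinom(n_samples, depth, p))
  dimnames(m) <- list(sprintf("s%02d", seq_len(n_samples)),
                      sprintf("t%02d", seq_len(n_taxa)))
  featureTable(m)
}

# star phylogeny: all tips equidistant
starTree <- function(n) {
  txt <- paste0("(", paste0("t", seq_len(n), ":1", collapse = ","), ");")
  ape::read.tree(text = txt)
}

# two deep star clades of n1 and n2 tips
twoCladeTree <- function(n1 = 30, n2 = 30) {
  a <- paste0("a", seq_len(n1), ":0.1", collapse = ",")
  b <- paste0("b", seq_len(n2), ":0.1", collapse = ",")
  ape::read.tree(text = sprintf("((%s):10,(%s):10);", a, b))
}

# brute-force transition counting oracle: enumerate subject series and
# count consecutive-day state pairs directly
oracleTransitionCounts <- function(labels, design, states) {
  grid <- sort(unique(design$day))
  C <- matrix(0L, length(states), length(states),
              dimnames = list(states, states))
  for (s in unique(design$subject_id)) for (h in unique(design$habitat)) {
    sub <- design[design$subject_id == s & design$habitat == h, ]
    for (i in seq_len(length(grid) - 1L)) {
      id1 <- sub$sample_id[sub$day == grid[i]]
      id2 <- sub$sample_id[sub$day == grid[i + 1L]]
      if (length(id1) == 1L && length(id2) == 1L &&
          id1 %in% names(labels) && id2 %in% names(labels)) {
        C[as.character(labels[[id1]]), as.character(labels[[id2]])] <-
          C[as.character(labels[[id1]]), as.character(labels[[id2]])] + 1L
      }
    }
  }
  C
}

# brute-force PERMANOVA pseudo-F for a fixed labelling
oracleF <- function(d, labels) {
  d <- as.matrix(d)
  n <- nrow(d)
  g <- unique(labels)
  sst <- sum(d^2) / (2 * n)
  ssw <- 0
  for (gr in g) {
    idx <- which(labels == gr)
    ssw <- ssw + sum(d[idx, idx]^2) / (2 * length(idx))
  }
  ((sst - ssw) / (length(g) - 1)) / (ssw / (n - length(g)))
}
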