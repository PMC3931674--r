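suppressPackageStartupMessages(library(SummarizedExperiment))

# Independent brute-force implementations used as oracles. They share
# no code with the package: ranks are counted pair by pair, rank
# products are plain products taken to the 1/K power, and the
# permutation analysis enumerates label assignments explicitly.

# rank of each gene's fold change within one comparison, rank 1 = the
# strongest in the requested direction, average ranks on ties
oracleComparisonRanks <- function(fc, direction) {
  vapply(seq_along(fc), function(g) {
    better <- if (direction == "up") sum(fc > fc[g]) else sum(fc < fc[g])
    tied <- sum(fc == fc[g]) - 1
    1 + better + tied / 2
  }, numeric(1))
}

oracleRankProduct <- function(expr, labels, direction) {
  labels <- as.factor(labels)
  ctrl <- which(labels == levels(labels)[1])
  case <- which(labels == levels(labels)[2])
  K <- length(ctrl) * length(case)
  rp <- rep(1, nrow(expr))
  for (i in ctrl) for (j in case) {
    fc <- expr[, j] - expr[, i]
    rp <- rp * oracleComparisonRanks(fc, direction)^(1 / K)
  }
  unname(rp)
}

# exhaustive permutation analysis: every way of choosing the control
# samples; counts use a 10-decimal rounding before comparison, as the
# package documents for tie stabilization
oraclePfp <- function(expr, labels, direction) {
  labels <- as.factor(labels)
  n0 <- sum(labels == levels(labels)[1])
  n <- length(labels)
  G <- nrow(expr)
  obs <- round(oracleRankProduct(expr, labels, direction), 10)
  assignments <- utils::combn(n, n0, simplify = FALSE)
  counts <- numeric(G)
  for (a in assignments) {
    lab <- rep("case", n)
    lab[a] <- "ctrl"
    star <- round(oracleRankProduct(expr, factor(lab, c("ctrl", "case")),
                                    direction), 10)
    for (g in seq_len(G)) counts[g] <- counts[g] + sum(star <= obs[g])
  }
  cc <- counts / length(assignments)
  r <- vapply(seq_len(G), function(g) sum(obs <= obs[g]), numeric(1))
  raw <- cc / r
  ord <- order(obs)
  pfp <- raw
  run <- -Inf
  for (g in ord) {
    run <- max(run, raw[g])
    pfp[g] <- run
  }
  list(pfp = pfp, pval = cc / G)
}

# small deterministic expression fixture: G genes x n samples
toyMatrix <- function(G, n, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rnorm(G * n), G, n,
              dimnames = list(sprintf("g%02d", seq_len(G)),
                              sprintf("s%02d", seq_len(n))))
  m
}

# compact synthetic study for pipeline tests
smallStudy <- function(seed = 1, ...) {
  simulateStudy(simulationConfig(
    nGenes = 200L, samplesPerStage = c(II = 12L, III = 12L, IV = 12L),
    nUpAmplified = 20L, nDownDeleted = 20L, nDeOnly = 20L,
    nCnaOnly = 20L, seed = seed, ...))
}

trueGenes <- function(truth, classes) truth$gene_id[truth$class %in% classes]
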