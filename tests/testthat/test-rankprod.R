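test_that("degenerate inputs are rejected", {
  m <- toyMatrix(4, 6)
  expect_error(rankProduct(m, rep("a", 6)), "two classes")
  expect_error(rankProduct(m, c("a", rep("b", 5))), "two samples per class")
  m[1, 1] <- NA
  expect_error(rankProduct(m, rep(c("a", "b"), each = 3)), "missing")
  expect_error(estimatePfp(toyMatrix(4, 6), rep(c("a", "b"), each = 3),
                           nPerm = 0), "nPerm")
})

test_that("a gene ranked first in every comparison attains RP = 1", {
  m <- rbind(g1 = c(0, 0, 10, 10),   # strongest up-regulation everywhere
             g2 = c(5, 5, 6, 6),
             g3 = c(7, 7, 5, 5))
  colnames(m) <- paste0("s", 1:4)
  rp <- rankProduct(m, factor(c("ctrl", "ctrl", "case", "case"),
                              levels = c("ctrl", "case")), "up")
  expect_equal(unname(rp["g1"]), 1)
  expect_true(all(rp >= 1))
})

test_that("rank products equal the brute-force enumeration oracle", {
  for (seed in 1:4) {
    m <- toyMatrix(3, 4, seed = seed)
    lab <- rep(c("ctrl", "case"), each = 2)
    expect_equal(unname(rankProduct(m, lab, "up")),
                 oracleRankProduct(m, lab, "up"))
    expect_equal(unname(rankProduct(m, lab, "down")),
                 oracleRankProduct(m, lab, "down"))
  }
  # unbalanced classes and ties
  m <- matrix(c(1, 1, 2, 2, 3, 3,
                4, 4, 4, 4, 4, 4,
                2, 1, 5, 1, 2, 5), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:6)))
  lab <- c("ctrl", "ctrl", "case", "case", "case", "case")
  expect_equal(unname(rankProduct(m, lab, "up")),
               oracleRankProduct(m, lab, "up"))
})

test_that("RP is invariant to sample order within classes and to monotone transforms", {
  m <- toyMatrix(5, 6, seed = 2)
  lab <- rep(c("ctrl", "case"), each = 3)
  rp <- rankProduct(m, lab, "up")
  perm <- c(3, 1, 2, 6, 4, 5)          # shuffle within each class
  expect_equal(rankProduct(m[, perm], lab[perm], "up"), rp)
  # strictly increasing transform of the values preserves all FC ranks
  # only if applied per comparison; a global affine map always does
  expect_equal(rankProduct(3 * m + 2, lab, "up"), rp)
})

test_that("exhaustive pfp and p-values match the enumeration oracle exactly", {
  for (seed in c(1, 7)) {
    m <- toyMatrix(5, 6, seed = seed)
    lab <- rep(c("ctrl", "case"), each = 3)
    got <- estimatePfp(m, lab)           # C(6,3) = 20 -> exhaustive
    expect_true(attr(got, "exhaustive"))
    oUp <- oraclePfp(m, lab, "up")
    oDown <- oraclePfp(m, lab, "down")
    expect_equal(got$pfp_up, oUp$pfp)
    expect_equal(got$pval_up, oUp$pval)
    expect_equal(got$pfp_down, oDown$pfp)
    expect_equal(got$pval_down, oDown$pval)
  }
})

test_that("pfp is monotone along the RP ranking and pfp estimation is seed-reproducible", {
  m <- toyMatrix(20, 10, seed = 4)
  lab <- rep(c("ctrl", "case"), each = 5)
  a <- estimatePfp(m, lab, nPerm = 25, seed = 99, exhaustiveLimit = 10)
  b <- estimatePfp(m, lab, nPerm = 25, seed = 99, exhaustiveLimit = 10)
  expect_false(attr(a, "exhaustive"))
  expect_identical(a, b)
  ord <- order(a$rp_up)
  expect_true(all(diff(a$pfp_up[ord]) >= 0))
  ord <- order(a$rp_down)
  expect_true(all(diff(a$pfp_down[ord]) >= 0))
})

test_that("selection behaves at the cutoff extremes and enriches planted genes", {
  st <- smallStudy(seed = 21)
  de <- rankProductDE(st$expression[[1]], progressionTask("II", "IV"),
                      nPerm = 40, seed = 1)
  all <- selectDE(de, alpha = 1.0)
  expect_setequal(union(all$up, all$down), st$truth$gene_id)
  tiny <- selectDE(de, alpha = min(de@table$pval_up[de@table$pval_up > 0],
                                   de@table$pval_down[de@table$pval_down > 0]))
  expect_true(length(tiny$up) < nrow(de@table) / 10)
  sel <- selectDE(de, alpha = 0.01)
  upTrue <- st$truth$gene_id[(st$truth$class == "up_amplified") |
    (st$truth$class == "de_only" & st$truth$direction == "up")]
  nullg <- trueGenes(st$truth, "null")
  rateTrue <- mean(upTrue %in% sel$up)
  rateNull <- mean(nullg %in% sel$up)
  expect_gt(rateTrue, 10 * max(rateNull, 1e-6))
})

test_that("cross-cohort intersection is direction-consistent set algebra", {
  expect_equal(
    intersectCohortSets(list(list(up = c("A", "B"), down = "X"),
                             list(up = c("B", "C"), down = c("X", "Y")))),
    list(up = "B", down = "X"))
  same <- list(up = c("A", "B"), down = "C")
  expect_equal(intersectCohortSets(list(same, same)), same)
  out <- intersectCohortSets(list(list(up = "A", down = "B"),
                                  list(up = "C", down = "D")))
  expect_length(out$up, 0)
  expect_length(out$down, 0)
  expect_error(intersectCohortSets(list()), "at least one")
  expect_error(intersectCohortSets(list(same)), "two cohorts")
})
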