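test_that("the default cost grid carries exactly 1101 positive values", {
  g <- svmGrid()
  expect_equal(nModels(g), 1101L)
  expect_equal(g@cValues[1101], 10000)
  expect_true(all(g@cValues > 0))                # non-positives clamped
  expect_equal(sum(abs(g@cValues - 1e-3) < 1e-12), 2L)  # -10 and -0.9
  expect_equal(diff(seq(-10, 10000, length.out = 1101))[1], 10010 / 1100)
})

test_that("the rank AUC equals pROC and inverts with the labels", {
  skip_if_not_installed("pROC")
  set.seed(12)
  for (i in 1:5) {
    y <- rep(c(0, 1), times = c(8, 12))
    s <- stats::rnorm(20) + y     # informative scores with possible ties
    s[1:3] <- s[4:6]              # force ties
    a <- cnaDissim:::.aucScore(s, y)
    expect_equal(a, as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                   direction = "<"))))
    expect_equal(cnaDissim:::.aucScore(s, 1 - y), 1 - a)
  }
})

test_that("fold assignment is stratified and reproducible", {
  y <- rep(c(0, 1), times = c(30, 20))
  f1 <- cnaDissim:::.stratifiedFolds(y, 10, seed = 3)
  f2 <- cnaDissim:::.stratifiedFolds(y, 10, seed = 3)
  expect_identical(f1, f2)
  for (k in 1:10) {
    expect_equal(sum(y == 0 & f1 == k), 3)
    expect_equal(sum(y == 1 & f1 == k), 2)
  }
})

test_that("a feature equal to the label yields AUC 1 at any cost", {
  y <- rep(c(0, 1), each = 10)
  x <- matrix(y + stats::rnorm(20, 0, 1e-3), ncol = 1)
  r <- evaluateAUC(x, y, grid = svmGrid(0.01, 1000, 3L), k = 5, seed = 1)
  expect_equal(r$auc, 1)
  expect_true(all(r$aucByC == 1))
})

test_that("the grid optimum dominates every single fixed cost and is reproducible", {
  set.seed(8)
  x <- matrix(stats::rnorm(40 * 4), 40, 4)
  y <- rep(c(0, 1), each = 20)
  x[, 1] <- x[, 1] + 0.8 * y
  grid <- svmGrid(0.1, 50, 4L)
  full <- evaluateAUC(x, y, grid = grid, k = 5, seed = 2)
  expect_equal(full$nModels, 5L)
  for (C in grid@cValues) {
    single <- evaluateAUC(x, y, grid = svmGrid(C, C + 1e-9, 1L),
                          k = 5, seed = 2)
    expect_gte(full$auc + 1e-12, single$aucByC[[1]])
  }
  again <- evaluateAUC(x, y, grid = grid, k = 5, seed = 2)
  expect_identical(full, again)
  expect_error(evaluateAUC(x, rep(1, 40), grid = grid), "both classes")
})

test_that("feature extraction produces the documented datatype shapes", {
  st <- smallStudy(seed = 14)
  co <- st$expression[[1]]
  task <- progressionTask("II", "III")
  truth <- st$truth
  sig <- new("CombinedSignature", task = task,
             upAmplified = trueGenes(truth, "up_amplified"),
             downDeleted = trueGenes(truth, "down_deleted"))
  deSets <- list(up = c(trueGenes(truth, "up_amplified"),
                        truth$gene_id[truth$class == "de_only" &
                                        truth$direction == "up"]),
                 down = c(trueGenes(truth, "down_deleted"),
                          truth$gene_id[truth$class == "de_only" &
                                          truth$direction == "down"]))
  m <- sum(stages(co) %in% c("II", "III"))

  sa <- extractFeatures(co, "NCOMB", task, deSets = deSets)
  expect_equal(dim(sa$x), c(m, length(union(deSets$up, deSets$down))))
  expect_equal(sum(sa$y), sum(stages(co) == "III"))

  comb <- extractFeatures(co, "COMB", task, signature = sig)
  expect_equal(dim(comb$x), c(m, length(signatureGenes(sig))))
  # SA features contain the COMB features whenever signature genes are DE
  expect_true(all(colnames(comb$x) %in% colnames(sa$x)))

  ra <- extractFeatures(co, "COMBDE", task, signature = sig)
  nProto <- sum(stages(co) == "II")
  expect_equal(dim(ra$x), c(m, nProto))
  # delegation: identical to building the dissimilarity matrix directly
  protos <- selectPrototypes(co, "II", signatureGenes(sig))
  D <- dissimilarityMatrix(
    assay(co, "exprs")[signatureGenes(sig),
                       stages(co) %in% c("II", "III")], protos,
    "euclidean")
  expect_equal(ra$x, D@.Data)

  expect_error(extractFeatures(co, "NCOMB", task,
                               deSets = list(up = character(0),
                                             down = character(0))),
               "empty gene set")
  empty <- new("CombinedSignature", task = task,
               upAmplified = character(0), downDeleted = character(0))
  expect_error(extractFeatures(co, "COMBDM", task, signature = empty),
               "signature is empty")
  expect_error(extractFeatures(co, "BOGUS", task), "unknown criterion")
})

test_that("the factorial experiment covers criteria x datasets x tasks", {
  st <- simulateStudy(simulationConfig(
    nExpressionCohorts = 3L, nGenes = 120L,
    samplesPerStage = c(II = 10L, III = 10L, IV = 10L),
    nUpAmplified = 15L, nDownDeleted = 15L, nDeOnly = 10L,
    nCnaOnly = 10L, seed = 23))
  truth <- st$truth
  tasks <- defaultTasks()
  sigs <- lapply(tasks, function(t)
    new("CombinedSignature", task = t,
        upAmplified = trueGenes(truth, "up_amplified"),
        downDeleted = trueGenes(truth, "down_deleted")))
  names(sigs) <- vapply(tasks, taskLabel, character(1))
  deSets <- lapply(sigs, function(s)
    list(up = s@upAmplified, down = s@downDeleted))
  tab <- runExperiment(st$expression, deSets, sigs, tasks = tasks,
                       grid = svmGrid(0.1, 10, 2L), k = 5, seed = 4)
  expect_equal(nrow(tab), 6 * 3 * 3)
  expect_equal(anyDuplicated(tab[, c("criterion", "dataset", "task")]), 0L)
  expect_true(all(is.na(tab$auc) | (tab$auc >= 0 & tab$auc <= 1)))
  expect_true(all(is.na(tab$error)))
  expect_true(all(tab$n_models == 3L))
  # rerun with the same seed reproduces the table exactly
  tab2 <- runExperiment(st$expression, deSets, sigs, tasks = tasks,
                        grid = svmGrid(0.1, 10, 2L), k = 5, seed = 4)
  expect_identical(tab, tab2)
})

test_that("cell failures are recorded without aborting the run", {
  st <- smallStudy(seed = 30)
  task <- progressionTask("II", "III")
  sigs <- list(new("CombinedSignature", task = task,
                   upAmplified = character(0),
                   downDeleted = character(0)))
  names(sigs) <- taskLabel(task)
  deSets <- list(list(up = st$truth$gene_id[1:5], down = character(0)))
  names(deSets) <- taskLabel(task)
  expect_warning(
    tab <- runExperiment(st$expression[1], deSets, sigs,
                         tasks = list(task),
                         criteria = c("NCOMB", "COMB"),
                         grid = svmGrid(1, 2, 1L), k = 3, seed = 1),
    "failed")
  expect_equal(nrow(tab), 2)
  expect_true(is.na(tab$auc[tab$criterion == "COMB"]))
  expect_match(tab$error[tab$criterion == "COMB"], "empty")
  expect_false(is.na(tab$auc[tab$criterion == "NCOMB"]))
})
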