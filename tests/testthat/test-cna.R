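test_that("threshold calls follow the call definition", {
  expect_true(all(callAlterations(rep(0, 5)) == "neutral"))
  expect_equal(unname(callAlterations(c(1.0, -1.0, 0.1))),
               c("gain", "loss", "neutral"))
  # boundary values are included
  expect_equal(unname(callAlterations(c(0.3, -0.3))), c("gain", "loss"))
  expect_error(callAlterations(0, gainThr = -0.1), "thresholds")
  expect_error(callAlterations(0, lossThr = 0.1), "thresholds")
})

test_that("within-sample calls are exclusive and recurrence counts samples", {
  m <- matrix(c(0.5, 0.1, 0.1, 0.1,     # gained in 1 of 4 samples
                -0.5, -0.5, -0.5, 0.0,  # lost in 3 of 4
                0.0, 0.0, 0.0, 0.0),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("gA", "gB", "gC"), paste0("s", 1:4)))
  calls <- callAlterations(m)
  expect_false(any(calls == "gain" & calls == "loss"))
  expect_equal(recurrentGenes(calls, minFreq = 0.25)$gain, "gA")
  expect_equal(recurrentGenes(calls, minFreq = 0.3)$gain, character(0))
  expect_equal(recurrentGenes(calls, minFreq = 0.75)$loss, "gB")
  r <- recurrentGenes(calls, minFreq = 1e-9)
  expect_setequal(r$gain, "gA")          # any single gain call suffices
  one <- matrix(rep(c("gain", "neutral"), 3), 3, 2, byrow = TRUE,
                dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  expect_equal(recurrentGenes(one, minFreq = 1.0)$gain, character(0))
  expect_error(recurrentGenes(matrix(character(0), 0, 0)), "non-empty")
})

test_that("cross-cohort support counting matches a brute-force membership oracle", {
  sets <- list(list(gain = c("A", "B"), loss = c("X")),
               list(gain = c("B", "C"), loss = c("X", "Y")),
               list(gain = c("A", "B"), loss = c("Z")))
  got <- crossCohortAltered(sets, minDatasets = 2)
  expect_equal(got$amplified, c("A", "B"))
  expect_equal(got$deleted, "X")
  # randomized sets vs direct counting
  set.seed(5)
  universe <- sprintf("g%02d", 1:40)
  rsets <- lapply(1:3, function(i)
    list(gain = sample(universe, 15), loss = sample(universe, 15)))
  for (md in 1:3) {
    got <- crossCohortAltered(rsets, minDatasets = md)
    amp <- sort(Filter(function(g)
      sum(vapply(rsets, function(s) g %in% s$gain, logical(1))) >= md,
      universe))
    del <- sort(Filter(function(g)
      sum(vapply(rsets, function(s) g %in% s$loss, logical(1))) >= md,
      universe))
    expect_equal(got$amplified, amp)
    expect_equal(got$deleted, del)
  }
  expect_error(crossCohortAltered(sets, minDatasets = 4), "between 1")
  expect_error(crossCohortAltered(list(), 1), "at least one")
})

test_that("raising minFreq or minDatasets never enlarges the output sets", {
  st <- smallStudy(seed = 8)
  task <- progressionTask("II", "IV")
  prev <- NULL
  for (mf in c(0.1, 0.25, 0.5)) {
    cur <- cnaAlteredSets(st$cna, task = task, minFreq = mf)
    if (!is.null(prev)) {
      expect_true(all(cur$amplified %in% prev$amplified))
      expect_true(all(cur$deleted %in% prev$deleted))
    }
    prev <- cur
  }
  prev <- NULL
  for (md in 1:3) {
    cur <- cnaAlteredSets(st$cna, task = task, minDatasets = md)
    if (!is.null(prev))
      expect_true(all(cur$amplified %in% prev$amplified))
    prev <- cur
  }
})

test_that("planted alterations are called at the penetrance rate and recovered", {
  hits <- freqs <- fps <- numeric(0)
  for (seed in 1:5) {
    st <- smallStudy(seed = seed)
    task <- progressionTask("II", "IV")
    co <- st$cna[[1]]
    caseIdx <- stages(co) == "IV"
    calls <- callAlterations(assay(co, "logratio")[, caseIdx])
    planted <- trueGenes(st$truth, "up_amplified")
    freqs <- c(freqs, rowMeans(calls[planted, ] == "gain"))
    sets <- cnaAlteredSets(st$cna, task = task)
    hits <- c(hits, mean(planted %in% sets$amplified))
    fps <- c(fps, mean(trueGenes(st$truth, "null") %in% sets$amplified))
  }
  expect_gte(mean(freqs), 0.8 - 0.1)     # penetrance minus tolerance
  expect_gte(mean(hits), 0.8)
  expect_lte(mean(fps), 0.05)
})
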