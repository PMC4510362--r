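# MCR engine: step satisfaction, completion ratios, matrices, abundance.

test_that("step satisfaction follows complex/alternative semantics", {
  cpx <- parse_definition("K00174+K00175+K00176+K00177")$children[[1]]
  # alpha and beta subunits alone do not satisfy the four-subunit complex
  expect_false(step_satisfied(cpx, c("K00174", "K00175")))
  expect_true(step_satisfied(cpx, c("K00174", "K00175", "K00176", "K00177")))

  alt <- parse_definition("K00850,K16370,K00918")$children[[1]]
  expect_false(step_satisfied(alt, character(0)))
  expect_true(step_satisfied(alt, "K00918"))

  opt <- parse_definition("K02025-K09999")$children[[1]]
  expect_true(step_satisfied(opt, "K02025"))   # optional subunit not required
  expect_false(step_satisfied(opt, "K09999"))  # mandatory subunit is

  expect_error(step_satisfied(defn_leaf("M00001"), "K00001"), "unresolved")
})

test_that("compute_mcr reproduces the worked-example ratios", {
  fx <- archaea_fixtures()

  r <- compute_mcr(fx$catalog$M00003, fx$profiles$csu, fx$catalog)
  expect_equal(r$total_steps, 7L)
  expect_equal(r$satisfied_steps, 6L)
  expect_equal(format_mcr(r$mcr), 85.7)
  expect_false(r$step_status[1])  # the carboxykinase step is the gap

  r <- compute_mcr(fx$catalog$M00001, fx$profiles$nmr, fx$catalog)
  expect_equal(r$mcr, 70)
  expect_equal(which(!r$step_status), c(1L, 3L, 10L))

  # full KO complement gives exactly 100
  for (m in fx$catalog) {
    all_kos <- definition_kos(m$definition)
    p <- genome_profile("complete", all_kos)
    expect_equal(compute_mcr(m, p, fx$catalog)$mcr, 100, info = m$module_id)
  }

  # empty profile gives 0
  expect_equal(compute_mcr(fx$catalog$M00001,
                           genome_profile("empty"), fx$catalog)$mcr, 0)
})

test_that("compute_mcr reports the missing KO sets of unsatisfied steps", {
  fx <- archaea_fixtures()
  r <- compute_mcr(fx$catalog$M00001, fx$profiles$csu, fx$catalog)
  # csu lacks only step 3; any one of the three kinases would complete it
  miss <- r$missing_kos[[3]]
  expect_setequal(unlist(miss), c("K00850", "K16370", "K00918"))
  expect_true(all(lengths(miss) == 1L))
})

test_that("display rounding is half-up at one decimal", {
  expect_equal(format_mcr(85.71428), 85.7)
  expect_equal(format_mcr(87.45), 87.5)
  expect_equal(format_mcr(100), 100)
})

test_that("MCR ignores copy counts but abundance does not", {
  m <- module_record("M00050", "K00001+K00002")
  p1 <- genome_profile("g1", c(K00001 = 1L, K00002 = 1L))
  p5 <- genome_profile("g5", c(K00001 = 5L, K00002 = 3L))
  expect_equal(compute_mcr(m, p1)$mcr, compute_mcr(m, p5)$mcr)
  expect_equal(module_abundance(m, p1), 1L)
  expect_equal(module_abundance(m, p5), 3L)  # bottleneck subunit
})

test_that("module abundance handles gaps, alternatives and shared KOs", {
  quad <- module_record("M00051", "K00001+K00002+K00003+K00004")
  p <- genome_profile("g", c(K00001 = 2L, K00002 = 3L, K00003 = 2L,
                             K00004 = 5L))
  expect_equal(module_abundance(quad, p), 2L)

  # one mandatory subunit absent entirely -> 0
  p0 <- genome_profile("g0", c(K00001 = 2L, K00002 = 3L, K00003 = 2L))
  expect_equal(module_abundance(quad, p0), 0L)

  # alternatives pool their copies: 2 by one branch + 1 by the other
  alt <- module_record("M00052", "K00001,K00002")
  p <- genome_profile("g", c(K00001 = 2L, K00002 = 1L))
  expect_equal(module_abundance(alt, p), 3L)

  # shared KO across steps: one copy serves both steps of one assignment
  shared <- module_record("M00053", "K00001 K00001,K00002")
  p <- genome_profile("g", c(K00001 = 1L))
  expect_equal(module_abundance(shared, p), 1L)
})

test_that("abundance equals the brute-force packing oracle on random modules", {
  set.seed(23)
  for (i in 1:60) {
    rd <- random_defn_text(max_leaves = 5L)
    m <- module_record("M00060", rd$text)
    counts <- stats::setNames(sample(0:3, length(rd$kos), replace = TRUE),
                              rd$kos)
    counts <- counts[counts > 0]
    p <- genome_profile("g", if (length(counts)) counts else integer(0))
    expect_equal(module_abundance(m, p),
                 oracle_abundance(rd$text, counts),
                 info = paste(rd$text, "counts:",
                              paste(names(counts), counts, collapse = " ")))
  }
})

test_that("abundance is at least 1 exactly when the MCR is 100", {
  set.seed(31)
  for (i in 1:40) {
    rd <- random_defn_text(max_leaves = 5L)
    m <- module_record("M00061", rd$text)
    kos <- sample(rd$kos, sample.int(length(rd$kos), 1L))
    p <- genome_profile("g", kos)
    mcr <- compute_mcr(m, p)$mcr
    ab <- module_abundance(m, p)
    expect_equal(ab >= 1L, mcr == 100, info = rd$text)
  }
})

test_that("adding KOs never decreases MCR or abundance", {
  set.seed(37)
  for (i in 1:60) {
    rd <- random_defn_text(max_leaves = 6L)
    m <- module_record("M00062", rd$text)
    base <- sample(rd$kos, sample.int(length(rd$kos), 1L))
    extra <- sample(rd$kos, 1L)
    p0 <- genome_profile("g", base)
    p1 <- genome_profile("g", unique(c(base, extra)))
    expect_gte(compute_mcr(m, p1)$mcr, compute_mcr(m, p0)$mcr)
    expect_gte(module_abundance(m, p1), module_abundance(m, p0))
  }
})

test_that("the MCR matrix preserves order and rejects duplicates", {
  fx <- archaea_fixtures()
  m <- compute_mcr_matrix(fx$catalog, fx$profiles)
  expect_equal(rownames(m), c("csu", "nmr", "nga", "csy"))
  expect_equal(colnames(m), names(fx$catalog))
  expect_true(all(m >= 0 & m <= 100))
  # cells equal the per-module computation
  expect_equal(m["csu", "M00003"],
               compute_mcr(fx$catalog$M00003, fx$profiles$csu, fx$catalog)$mcr)

  # permutation of profiles permutes rows only
  m2 <- compute_mcr_matrix(fx$catalog, rev(fx$profiles))
  expect_equal(m2[rownames(m), ], m)

  expect_error(compute_mcr_matrix(fx$catalog,
                                  list(fx$profiles$csu, fx$profiles$csu)),
               "duplicate genome_id")
  # 1 module x 1 empty profile
  one <- compute_mcr_matrix(fx$catalog["M00001"],
                            list(genome_profile("empty")))
  expect_equal(unname(one), matrix(0, 1, 1))
})

test_that("genome profiles validate their KO keys and counts", {
  expect_error(genome_profile("g", c(BAD = 1L)), "malformed KO")
  expect_error(genome_profile("g", c(K00001 = 0L)), ">= 1")
  p <- genome_profile("g", c("K00001", "K00002"))
  expect_equal(unname(p$ko_counts), c(1L, 1L))
})
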