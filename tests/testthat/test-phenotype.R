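panel_from <- function(mat, ...) {
  rownames(mat) <- paste0("st", seq_len(nrow(mat)))
  colnames(mat) <- paste0("R", seq_len(ncol(mat)))
  profile_panel(mat, ...)
}

test_that("thresholding is strict and zero rows warn but are retained", {
  m <- rbind(c(60, 60, 10), c(0, 0, 100))
  p <- panel_from(m, threshold = 50)
  expect_equal(unname(p$mask), rbind(c(TRUE, TRUE, FALSE),
                                     c(FALSE, FALSE, TRUE)))
  # a signal of exactly 50 is not utilization
  p2 <- panel_from(rbind(c(50, 60)), threshold = 50)
  expect_equal(unname(p2$mask[1, ]), c(FALSE, TRUE))
  expect_warning(pz <- panel_from(rbind(c(60, 0), c(0, 0))),
                 "no utilized resource")
  expect_equal(sum(pz$proportions[2, ]), 0)
  expect_true("st2" %in% pz$strains)
})

test_that("proportions renormalize over supra-threshold signals only", {
  p <- panel_from(rbind(c(60, 90, 10)), threshold = 50)
  expect_equal(unname(p$proportions[1, ]), c(60, 90, 0) / 150)
  expect_equal(sum(p$proportions[1, ]), 1)
  # the raw-signal convention keeps sub-threshold mass for comparison
  praw <- panel_from(rbind(c(60, 90, 10)), threshold = 50,
                     renormalize = FALSE)
  expect_equal(unname(praw$proportions[1, ]), c(60, 90, 10) / 160)
})

test_that("Levins width matches hand-evaluated cases and its bounds", {
  expect_equal(niche_width(c(0.5, 0.3, 0.2)), 1 / 0.38, tolerance = 1e-12)
  expect_equal(niche_width(rep(1 / 7, 7)), 7, tolerance = 1e-12)
  expect_equal(niche_width(c(1, 0, 0)), 1)
  expect_error(niche_width(c(0, 0)), "undefined")
  # scaling invariance and the 1 <= W <= count sandwich
  set.seed(3)
  for (i in 1:20) {
    k <- sample(2:12, 1)
    sig <- runif(k, 51, 300)
    pan <- panel_from(rbind(c(sig, rep(0, 3))))
    w <- unname(niche_width(pan)[1])
    expect_equal(w, unname(niche_width(panel_from(rbind(c(sig * 3.7,
                                                          rep(0, 3))))))[1],
                 tolerance = 1e-9)
    expect_gte(w, 1)
    expect_lte(w, unname(simplified_width(pan)[1]) + 1e-9)
  }
  # equality with the count holds exactly for uniform use
  pu <- panel_from(rbind(c(80, 80, 80, 0)))
  expect_equal(unname(niche_width(pu)[1]), 3, tolerance = 1e-12)
})

test_that("binary panels reduce Levins width to the utilized count", {
  p <- panel_from(rbind(c(1, 0, 1, 1)), binary = TRUE)
  expect_equal(unname(niche_width(p)[1]), 3)
  expect_equal(unname(simplified_width(p)[1]), 3L)
})

test_that("simplified width counts utilized resources", {
  p <- suppressWarnings(panel_from(rbind(c(60, 10, 70, 90),
                                         c(10, 20, 30, 40)),
                                   threshold = 50))
  expect_equal(unname(simplified_width(p)), c(3, 0))
})

test_that("Pianka overlap matches hand evaluation, symmetry and bounds", {
  expect_equal(pianka_overlap(c(0.5, 0.5, 0), c(0, 0.5, 0.5)), 0.5)
  expect_equal(pianka_overlap(c(0.2, 0.8), c(0.2, 0.8)), 1)
  expect_equal(pianka_overlap(c(1, 0), c(0, 1)), 0)
  expect_error(pianka_overlap(c(0, 0), c(1, 0)), "zero-norm")
  expect_error(pianka_overlap(c(1, 0), c(1, 0, 0)), "different resource")
  set.seed(9)
  for (i in 1:20) {
    a <- runif(6); b <- runif(6)
    expect_identical(pianka_overlap(a, b), pianka_overlap(b, a))
    o <- pianka_overlap(a, b)
    expect_gte(o, 0); expect_lte(o, 1)
  }
})

test_that("average overlap is the mean over partners", {
  m <- rbind(c(80, 80, 0, 0), c(80, 80, 0, 0), c(0, 80, 80, 0))
  p <- panel_from(m)
  M <- overlap_matrix(p)
  expect_equal(M, t(M))
  expect_equal(unname(diag(M)), rep(1, 3))
  expect_equal(average_overlap(p, "st1"),
               mean(c(M["st1", "st2"], M["st1", "st3"])))
  two <- panel_from(m[1:2, ])
  expect_equal(average_overlap(two, "st1"), M["st1", "st2"])
  expect_error(average_overlap(p, "ghost"), "unknown strain")
})

test_that("NSR/BSR classification is inclusive at both cutoffs", {
  expect_equal(as.character(classify_nsr_bsr(c(3, 15, 40))),
               c("NSR", "intermediate", "BSR"))
  expect_equal(as.character(classify_nsr_bsr(c(7, 29))), c("NSR", "BSR"))
  expect_equal(as.character(classify_nsr_bsr(rep(15, 3))),
               rep("intermediate", 3))
  expect_error(classify_nsr_bsr(1:3, low = 10, high = 10), "smaller")
})

test_that("the siderophore index is 1 - As/Ar with domain checks", {
  expect_equal(cas_siderophore_index(0.6, 0.6), 0)
  expect_equal(cas_siderophore_index(0, 0.6), 1)
  expect_equal(cas_siderophore_index(0.3, 0.6), 0.5)
  expect_error(cas_siderophore_index(0.3, 0), "positive")
  expect_error(cas_siderophore_index(-0.1, 0.5), "non-negative")
})

test_that("panels load from CSV with precise error reporting", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("strain,Ra,Rb,Rc", "s1,60,60,10", "s2,0,0,100"), f)
  p <- load_panel(f, threshold = 50)
  expect_equal(p$strains, c("s1", "s2"))
  expect_equal(unname(p$mask), rbind(c(TRUE, TRUE, FALSE),
                                     c(FALSE, FALSE, TRUE)))
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("strain,Ra,Rb", "s1,60,oops", "s2,1,2"), bad)
  expect_error(load_panel(bad), "strain 's1', resource 'Rb'")
  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("strain,Ra,Rb", "s1,1,2", "s1,3,4"), dup)
  expect_error(load_panel(dup), "duplicated strain")
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("strain,Ra", empty)
  expect_error(load_panel(empty), "empty")
})

test_that("panel_stats assembles the per-strain index table", {
  m <- rbind(c(80, 80, 80, 0), c(80, 0, 0, 0))
  p <- panel_from(m)
  tab <- panel_stats(p, low = 1, high = 3)
  expect_equal(tab$strain_id, c("st1", "st2"))
  expect_equal(tab$niche_width, c(3, 1))
  expect_equal(tab$simplified_width, c(3L, 1L))
  expect_equal(as.character(tab$class), c("BSR", "NSR"))
})
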