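mutual_pair <- function() {
  sp <- crossfeed_spec(2, list(c("S1", "S2", "x"), c("S2", "S1", "y")))
  make_crossfeeding_panel(sp)
}

test_that("merging two toys pools the environment in the interacting regime", {
  a <- toy_chain_model(id = "A")
  b <- toy_chain_model(id = "B")
  ci <- merge_community(list(a, b), "interacting")
  cn <- merge_community(list(a, b), "non_interacting")
  # 2 internal reactions per member, plus one pooled exchange when shared
  expect_equal(length(ci$merged$reactions), 2 * 2 + 1)
  expect_equal(length(cn$merged$reactions), 2 * 3)
  expect_equal(names(ci$env_map), "carbon_e")
  expect_length(cn$env_map$carbon_e, 2)
  expect_error(merge_community(list(a, a)), "collision")
  expect_error(merge_community(list(a)), "at least 2")
})

test_that("cross-feeding is possible only in the interacting regime", {
  pan <- mutual_pair()
  sc <- community_scores(pan$models)
  # shared pool: carbon alone suffices, exchanged metabolites are spared
  expect_equal(sc$media_detail$interacting, "carbon_e")
  # private pools: both auxotrophic metabolites must come from outside
  expect_setequal(sc$media_detail$non_interacting,
                  c("carbon_e", "x_e", "y_e"))
  expect_equal(sc$mip, 2L)
})

test_that("self-sufficient duplicates have nothing to exchange", {
  a <- toy_chain_model(id = "A")
  b <- toy_chain_model(id = "B")
  sc <- community_scores(list(a, b))
  expect_equal(sc$mip, 0L)
  expect_equal(sc$mro, 1)    # identical minimal media
})

test_that("engineered exchange chains recover their ground-truth MIP", {
  for (k in 2:5) {
    sp <- crossfeed_spec(k, lapply(seq_len(k - 1), function(i) {
      c(paste0("S", i), paste0("S", i + 1), paste0("m", i))
    }))
    pan <- make_crossfeeding_panel(sp)
    expect_equal(mip_score(pan$models),
                 ground_truth_mip(sp, sp$strain_ids),
                 info = paste("chain length", k))
  }
})

test_that("regime media sizes match exhaustive search on the mutual pair", {
  pan <- mutual_pair()
  expect_equal(
    length(community_scores(pan$models)$media_detail$non_interacting),
    brute_force_community_medium_size(pan$models, "non_interacting"))
  expect_equal(
    length(community_scores(pan$models)$media_detail$interacting),
    brute_force_community_medium_size(pan$models, "interacting"))
})

test_that("MRO spans its boundary cases", {
  # identical members -> 1
  expect_equal(mro_score(list(toy_chain_model(id = "A"),
                              toy_chain_model(id = "B"))), 1)
  # disjoint sole carbon sources -> 0
  expect_equal(mro_score(list(sole_carbon_model("glc"),
                              sole_carbon_model("xyl"))), 0)
  # shared carbon, private auxotrophies: intersection 1 of mean size 2
  expect_equal(mro_score(mutual_pair()$models), 0.5)
})

test_that("member order never changes community scores", {
  sp <- crossfeed_spec(3, list(c("S1", "S2", "x"), c("S2", "S3", "y")))
  pan <- make_crossfeeding_panel(sp)
  sc1 <- community_scores(pan$models[c("S1", "S2", "S3")])
  sc2 <- community_scores(pan$models[c("S3", "S1", "S2")])
  expect_equal(sc1$mip, sc2$mip)
  expect_equal(sc1$mro, sc2$mro)
  expect_setequal(sc1$media_detail$non_interacting,
                  sc2$media_detail$non_interacting)
})

test_that("community enumeration counts and orders subsets deterministically", {
  expect_length(enumerate_communities(paste0("s", 1:6), 2, 6), 57)
  subs <- enumerate_communities(c("a", "b", "c"), 2, 3)
  expect_equal(subs, list(c("a", "b"), c("a", "c"), c("b", "c"),
                          c("a", "b", "c")))
  expect_length(enumerate_communities(paste0("t", 1:224), 2, 2), 24976)
  expect_error(enumerate_communities(letters[1:4], 3, 2), "min_size")
  expect_error(enumerate_communities(letters[1:4], 1, 3), "at least 2")
})

test_that("score_all validates inputs up front and aggregates by size", {
  sp <- crossfeed_spec(3, list(c("S1", "S2", "x"), c("S2", "S3", "y")))
  pan <- make_crossfeeding_panel(sp)
  expect_error(score_all(pan$models, list(c("S1", "ghost"))),
               "no model for member")
  tab <- score_all(pan$models,
                   enumerate_communities(sp$strain_ids, 2, 3))
  expect_equal(nrow(tab), 4)
  expect_true(all(tab$mip >= 0))
  expect_true(all(tab$mro >= 0 & tab$mro <= 1))
  # the full chain spares both engineered exchanges
  expect_equal(tab$mip[tab$members == "S1;S2;S3"], 2L)
  expect_equal(tab$mip[tab$members == "S1;S3"], 0L)
})

test_that("dropping the sole donor collapses MIP; redundant members do not", {
  sp <- crossfeed_spec(3, list(c("S1", "S2", "x")))
  pan <- make_crossfeeding_panel(sp)
  scan <- dropout_scan(pan$models, c("S1", "S2", "S3"))
  expect_equal(nrow(scan), 4)               # full set + one row per member
  expect_equal(scan$mip[scan$dropped == ""], 1L)
  expect_equal(scan$mip[scan$dropped == "S1"], 0L)    # donor gone
  expect_equal(scan$delta_mip[scan$dropped == "S3"], 0)  # bystander
})

test_that("ranking prefers high MIP, then low MRO, then member order", {
  tab <- data.frame(
    members = c("a;b", "a;c", "b;c", "a;d"),
    size = 2,
    mip = c(4L, 1L, 4L, 4L),
    mro = c(0.77, 0.50, 0.84, 0.77))
  ranked <- rank_communities(tab)
  expect_equal(ranked$members, c("a;b", "a;d", "b;c", "a;c"))
  expect_error(rank_communities(tab[0, ]), "empty")
})
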