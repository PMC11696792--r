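test_that("fragment delimitation follows the overlapping-window formula", {
  fs <- make_fragments(1046, 15, 100)
  expect_equal(nrow(fs), 15)
  expect_equal(c(fs$start[1], fs$end[1]), c(1, 100))
  expect_equal(c(fs$start[15], fs$end[15]), c(947, 1046))
  # coverage of [1, length] with 32-33 residue overlaps
  expect_true(all(fs$start[-1] <= fs$end[-15]))
  ov <- fs$end[-15] - fs$start[-1] + 1
  expect_true(all(ov %in% c(32, 33)))
  expect_true(all(diff(fs$start) %in% c(67, 68)))
  cov <- rep(FALSE, 1046)
  for (i in seq_len(15)) cov[fs$start[i]:fs$end[i]] <- TRUE
  expect_true(all(cov))
  # single-fragment edge case and determinism
  f1 <- make_fragments(100, 1, 100)
  expect_equal(c(f1$start, f1$end), c(1, 100))
  expect_identical(make_fragments(1046, 15, 100), fs)
  expect_error(make_fragments(500, 4, 100), "cannot cover")
})

test_that("automatic fragment count keeps at least the minimum overlap", {
  fs <- make_fragments(350, target_len = 100, min_overlap = 20)
  ov <- fs$end[-nrow(fs)] - fs$start[-1] + 1
  expect_true(all(ov >= 19))  # rounding can shave one residue
  expect_true(fs$end[nrow(fs)] == 350 && fs$start[1] == 1)
})

test_that("explicit domain delimitations are accepted verbatim", {
  dl <- rbind(c(1, 41), c(32, 95), c(86, 115), c(106, 142))
  expect_warning(fs <- make_fragments(143, delimitations = dl), "cover")
  expect_equal(fs$start, c(1, 32, 86, 106))
  expect_equal(fs$end, c(41, 95, 115, 142))
  expect_error(make_fragments(143, delimitations = rbind(c(1, 41), c(50, 80))),
               "overlap")
})

test_that("MSA filtering applies identity, coverage and species rules", {
  msa <- species_msa(
    c("MKLVQACDEF",   # query
      "MKLVQACDEF",   # exact duplicate of query sequence
      "MKIVQACDEF",   # mouse, 90% id
      "MKIVQARDEF",   # mouse, 80% id -> dropped (one per species)
      "M---------",   # fly, coverage 10 -> dropped
      "AAAAAAAAAA",   # frog, 0% id -> dropped (below qid)
      "MKLVAACDEF"),  # frog, 90% id
    c("human", "human2", "mouse", "mouse", "fly", "frog", "frog"))
  out <- filter_msa(msa, qid = 25, cov = 50)
  expect_equal(out$species, c("human", "mouse", "frog"))
  expect_equal(out$identity[out$species == "mouse"], 90)
  expect_equal(out$sequence[out$species == "frog"], "MKLVAACDEF")
  expect_error(filter_msa(msa[0, ]), "query")
})

test_that("species pairing enumerates paired and padded rows exactly", {
  a <- species_msa(c("AAAA", "CCCC", "GGGG"), c("qa", "human", "mouse"))
  b <- species_msa(c("WWW", "YYY", "FFF"), c("qb", "mouse", "fly"))
  co <- pair_msas(a, b)
  expect_equal(nrow(co), 4)  # query pair, mouse paired, human, fly
  expect_true(all(nchar(co$sequence) == 7))
  expect_equal(co$sequence[1], "AAAAWWW")
  expect_equal(co$sequence[co$species == "mouse"], "GGGGYYY")
  expect_equal(co$sequence[co$species == "human"], "CCCC---")
  expect_equal(co$sequence[co$species == "fly"], "----FFF")
  # disjoint species: only the query row is paired
  b2 <- species_msa(c("WWW", "YYY"), c("qb", "worm"))
  co2 <- pair_msas(a, b2)
  expect_true(all(is.na(co2$id_b[co2$species %in% c("human", "mouse")])))
  # identical species sets of size k: k paired rows + query row
  b3 <- species_msa(c("WWW", "YYY", "FFF"), c("qb", "human", "mouse"))
  expect_equal(nrow(pair_msas(a, b3)), 3)
  expect_error(pair_msas(a[0, ], b), "empty")
})

test_that("confidence aggregation follows the 20:80 pTM/ipTM weighting", {
  s <- aggregate_scores(data.frame(plddt = rep(80, 5), ptm = rep(0.7, 5),
                                   iptm = rep(0.7, 5)))
  expect_equal(s$avg_iptm, 0.7)
  expect_equal(s$best_confidence, 0.7)
  s2 <- aggregate_scores(data.frame(plddt = 80, ptm = 0.5, iptm = 0.75))
  expect_equal(s2$best_confidence, 0.7)
  s3 <- aggregate_scores(data.frame(plddt = rep(70, 5), ptm = rep(0.5, 5),
                                    iptm = seq(0.1, 0.5, 0.1)))
  expect_equal(s3$avg_iptm, 0.3)
  expect_error(aggregate_scores(data.frame(plddt = 80, ptm = 1.2, iptm = 0.5)),
               "0, 1")
  # permutation invariance of model order
  perm <- aggregate_scores(data.frame(plddt = rep(70, 5), ptm = rep(0.5, 5),
                                      iptm = c(0.3, 0.5, 0.1, 0.4, 0.2)))
  expect_equal(perm$avg_iptm, s3$avg_iptm)
  expect_equal(perm$best_confidence, s3$best_confidence)
})

test_that("screening is strict at the 0.65 boundary", {
  mk <- function(conf, prey) {
    # ptm = iptm = conf makes the confidence equal conf exactly
    aggregate_scores(data.frame(plddt = 80, ptm = conf, iptm = conf),
                     prey = prey)
  }
  out <- screen_candidates(list(mk(0.66, "in"), mk(0.65, "boundary"),
                                mk(0.64, "out")))
  expect_equal(out$prey, "in")
  expect_equal(nrow(screen_candidates(list(mk(0.1, "a"), mk(0.2, "b")))), 0)
})

test_that("ranking equals a naive sort oracle on random score tables", {
  set.seed(17)
  sets <- lapply(1:10, function(i) {
    aggregate_scores(data.frame(plddt = runif(5, 50, 95), ptm = runif(5),
                                iptm = runif(5)),
                     bait = "b1", prey = sprintf("prey%02d", i))
  })
  out <- screen_candidates(sets, threshold = 0, rank_by = "avg_iptm",
                           select_by = "avg_iptm")
  oracle <- data.frame(prey = vapply(sets, `[[`, "", "prey"),
                       avg = vapply(sets, `[[`, 0, "avg_iptm"))
  oracle <- oracle[order(-oracle$avg), ]
  expect_equal(out$prey, oracle$prey)
  # monotonicity: raising any ipTM never lowers avg_iptm
  raised <- sets[[3]]$models
  raised$iptm <- pmin(raised$iptm + 0.1, 1)
  s_up <- aggregate_scores(raised[, c("plddt", "ptm", "iptm")])
  expect_gte(s_up$avg_iptm, sets[[3]]$avg_iptm)
})

test_that("the mock predictor replays its fixture table through the screen", {
  tab <- expand.grid(bait = "f10", prey = c("YWHAQ", "ACTB"), model = 1:5,
                     stringsAsFactors = FALSE)
  tab$plddt <- 80
  tab$ptm <- 0.6
  tab$iptm <- ifelse(tab$prey == "YWHAQ", 0.8, 0.3)
  pred <- mock_predictor(tab)
  hits <- run_screen("f10", c("YWHAQ", "ACTB"), pred)
  expect_equal(hits$prey, "YWHAQ")
  expect_equal(hits$best_confidence, 0.2 * 0.6 + 0.8 * 0.8)
  expect_error(pred("f10", "missing"), "no scores")
})
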