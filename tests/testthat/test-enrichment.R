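test_that("DE filter applies strict cut-offs on both axes", {
  tab <- data.frame(
    gene_id = paste0("g", 1:10),
    log2fc = c(2, -2, 1.0, -1.0, 3, -3, 0.2, 2, -2, 1.5),
    padj   = c(0.01, 0.01, 0.01, 0.01, 0.05, 0.2, 0.001, 0.049, 0.001, 0.04))
  res <- filter_de(tab)
  # hand enumeration: up needs padj < 0.05 AND log2fc > 1
  expect_setequal(res$up, c("g1", "g8", "g10"))
  expect_setequal(res$down, c("g2", "g9"))
  # boundary genes excluded: padj == 0.05 (g5), |lfc| == 1 (g3, g4)
  expect_false("g5" %in% c(res$up, res$down))
  expect_false(any(c("g3", "g4") %in% c(res$up, res$down)))

  # invariants: bounded size, permutation invariance, duplicate error
  expect_lte(length(res$up) + length(res$down), nrow(tab))
  perm <- tab[sample(nrow(tab)), ]
  res2 <- filter_de(perm)
  expect_setequal(res2$up, res$up)
  expect_setequal(res2$down, res$down)
  expect_error(filter_de(rbind(tab, tab[1, ])),
               class = "sealmito_invalid_input")
})

test_that("fisher_enrich equals the enumeration oracle on stated examples", {
  bg <- paste0("g", 1:20)
  # overlap 0 with nonempty sets -> p = 1
  res <- fisher_enrich(bg[1:5], bg[6:10], bg)
  expect_equal(res$overlap, 0)
  expect_equal(res$p, 1)
  # saturated: query == target == background
  res <- fisher_enrich(bg, bg, bg)
  expect_equal(res$p, 1)
  expect_equal(res$overlap, 20)
  # background 20, query 5, target 5, overlap 4
  res <- fisher_enrich(c(bg[1:4], bg[10]), bg[1:5], bg)
  expect_equal(res$overlap, 4)
  expect_equal(res$p, hyper_oracle(20, 5, 5, 4))
  # matches R's one-sided Fisher exact test
  ft <- fisher.test(matrix(c(4, 1, 1, 14), 2), alternative = "greater")
  expect_equal(res$p, ft$p.value)
  expect_error(fisher_enrich("a", "a", character(0)),
               class = "sealmito_invalid_input")
  expect_error(fisher_enrich("zz", bg[1:3], bg),
               class = "sealmito_invalid_input")
})

test_that("BH adjustment matches hand computation and reference", {
  expect_equal(bh_adjust(0.07), 0.07)
  expect_equal(bh_adjust(rep(0.03, 5)), rep(0.03, 5))
  # hand step-up for [0.01, 0.02, 0.03, 0.04]: p * 4 / rank = 0.04 each
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # property: equals stats::p.adjust, never decreases, order-preserving
  set.seed(71)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, p.adjust(p, "BH"))
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
  expect_error(bh_adjust(c(0.2, 1.4)), class = "sealmito_invalid_input")
})

test_that("combined score follows the documented sign convention", {
  expect_equal(combined_score(1, 5), 0)          # p = 1 -> 0 for any z
  expect_equal(combined_score(exp(-1), 2), -2)   # ln(p) * z, pinned
  expect_equal(combined_score(exp(-1), -2), 2)   # enriched z < 0 -> positive
  expect_warning(s0 <- combined_score(0, -1), "capped")
  expect_true(is.finite(s0) && s0 > 0)
  expect_error(combined_score(1.2, 1), class = "sealmito_invalid_input")
})

test_that("rank-deviation z is calibrated on null queries and seeded", {
  set.seed(202)
  bg <- paste0("g", 1:120)
  collection <- lapply(1:8, function(i) sample(bg, 25))
  names(collection) <- paste0("set", 1:8)
  mean_z <- vapply(1:50, function(s) {
    q <- withr::with_seed(1000 + s, sample(bg, 20))
    z <- rank_deviation_z(q, collection, bg, n_permutations = 100, seed = s)
    mean(z, na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(mean_z)), 0.2)

  # a set equal to the query is the most enriched: most negative z,
  # largest combined score
  q <- collection$set3
  z <- rank_deviation_z(q, collection, bg, n_permutations = 200, seed = 7)
  expect_equal(names(which.min(z)), "set3")
  p <- vapply(collection, function(s) fisher_enrich(q, s, bg)$p, numeric(1))
  expect_equal(names(which.max(combined_score(p, z))), "set3")

  # identical sets get identical z (mean rank on ties)
  twin <- collection; twin$set9 <- twin$set3
  z2 <- rank_deviation_z(q, twin, bg, n_permutations = 100, seed = 7)
  expect_equal(z2[["set3"]], z2[["set9"]])

  # deterministic given seed
  z3 <- rank_deviation_z(q, collection, bg, n_permutations = 100, seed = 7)
  z4 <- rank_deviation_z(q, collection, bg, n_permutations = 100, seed = 7)
  expect_identical(z3, z4)

  expect_error(rank_deviation_z(q, collection, bg, n_permutations = 50),
               class = "sealmito_invalid_input")
  expect_warning(z1 <- rank_deviation_z(q, collection["set1"], bg,
                                        n_permutations = 100, seed = 1),
                 "fewer than 2")
  expect_true(is.na(z1))
})

test_that("enrich ranks a spiked set first and writes consistent columns", {
  de <- simulate_de_table(1000, frac_up = 0.1, effect_lfc = 2, seed = 31)
  up <- filter_de(de)$up
  set.seed(32)
  sets <- c(list(spiked = c(sample(up, 25), sample(de$gene_id, 5))),
            lapply(1:5, function(i) sample(de$gene_id, 30)))
  names(sets)[-1] <- paste0("null", 1:5)
  res <- enrich(up, sets, background = de$gene_id,
                n_permutations = 150, seed = 33)
  expect_equal(res$set_name[1], "spiked")
  expect_lt(res$padj[1], 0.05)
  expect_true(all(res$overlap_count <= pmin(res$set_size, res$query_size)))
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_true(all(res$padj >= res$p - 1e-12))
})

test_that("GMT round-trips", {
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g4", "g5"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path, descriptions = c("first", "second"))
  back <- read_gmt(path)
  expect_equal(back[names(sets)], sets, ignore_attr = TRUE)
  expect_equal(attr(back, "descriptions")[["alpha"]], "first")
  writeLines("solo\tdesc", path)
  expect_error(read_gmt(path), class = "sealmito_io_error")
})
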