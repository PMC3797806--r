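toy_collection <- function(sets, universe) gene_set_collection(sets, universe)

test_that("Fisher enrichment reproduces the fully-overlapping worked case", {
  universe <- paste0("g", 1:10)
  coll <- toy_collection(list(S = paste0("g", 1:5)), universe)
  res <- fisher_enrichment(paste0("g", 1:5), coll)
  # N=10, K=5, n=5, k=5: p = C(5,5) C(5,0) / C(10,5) = 1/252
  expect_equal(res$p_value, 1 / 252, tolerance = 1e-12)
  expect_equal(res$k, 5)
  # set equal to the universe: p = 1 whatever the query
  coll2 <- toy_collection(list(ALL = universe), universe)
  expect_equal(fisher_enrichment(paste0("g", 1:3), coll2)$p_value, 1)
})

test_that("Fisher p equals exhaustive tail enumeration on random tables", {
  set.seed(17)
  for (rep in 1:200) {
    N <- sample(5:30, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    k <- sample(max(0, n + K - N):min(n, K), 1)
    p_pkg <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    expect_equal(p_pkg, oracle_hyper_tail(k, K, n, N), tolerance = 1e-12)
  }
  # and through the full function interface
  universe <- paste0("g", 1:20)
  coll <- toy_collection(list(S = paste0("g", 1:8)), universe)
  res <- fisher_enrichment(paste0("g", c(1:4, 15:18)), coll)
  expect_equal(res$p_value, oracle_hyper_tail(4, 8, 8, 20), tolerance = 1e-12)
})

test_that("chi-square enrichment matches hand arithmetic and flags degeneracy", {
  universe <- paste0("g", 1:60)
  # table (20,10,10,20): query g1..g30, set = g1..g20 + g51..g60
  coll <- toy_collection(list(S = paste0("g", c(1:20, 51:60))), universe)
  res <- chi2_enrichment(paste0("g", 1:30), coll)
  expect_equal(res$statistic, 100 / 15, tolerance = 1e-12)  # sum (O-E)^2/E
  expect_equal(res$p_value, pchisq(100 / 15, 1, lower.tail = FALSE))
  # balanced null table: statistic 0, p = 1
  coll2 <- toy_collection(list(S = paste0("g", c(1:15, 31:45))), universe)
  res2 <- chi2_enrichment(paste0("g", 1:30), coll2)
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p_value, 1)
  # degenerate margin: set = universe
  coll3 <- toy_collection(list(ALL = universe), universe)
  res3 <- chi2_enrichment(paste0("g", 1:30), coll3)
  expect_equal(res3$p_value, 1)
  expect_true(res3$unreliable)
})

test_that("chi-square and two-sided Fisher agree asymptotically", {
  set.seed(3)
  deltas <- vapply(c(200, 2000, 20000), function(N) {
    universe <- paste0("g", seq_len(N))
    K <- N / 4
    coll <- toy_collection(list(S = sample(universe, K)), universe)
    q <- sample(universe, N / 5)
    k <- length(intersect(q, coll$sets$S))
    m <- matrix(c(k, length(q) - k, K - k, N - K - length(q) + k), 2)
    p_f <- fisher.test(m, alternative = "two.sided")$p.value
    p_c <- chi2_enrichment(q, coll)$p_value
    abs(p_c - p_f)
  }, numeric(1))
  expect_lt(deltas[3], deltas[1] + 0.02)
  expect_lt(deltas[3], 0.02)
})

test_that("BH adjustment matches the step-up formula and is permutation invariant", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")

  # oracle: p_(i) * m / i with monotone enforcement from the largest down
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    pmin(1, adj)[order(o)]
  }
  set.seed(12)
  for (rep in 1:50) {
    p <- runif(sample(2:40, 1))
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
    perm <- sample(length(p))
    expect_equal(bh_fdr(p[perm]), bh_fdr(p)[perm], tolerance = 1e-12)
  }
})

test_that("neighbor query sets deduplicate and restrict to assigned neighbors", {
  classified <- data.frame(
    lncrna_id = c("l1", "l2", "l3", "l4"),
    positional_class = c("intergenic", "intergenic", "bidirectional",
                         "intergenic"),
    neighbor_gene_id = c("gA", "gA", "gB", NA),
    distance_bp = c(10, 20, 0, NA))
  ns <- neighbor_gene_sets(classified, up_ids = c("l1", "l2"),
                           down_ids = c("l3", "l4"))
  expect_identical(ns$up_genes, "gA")       # shared neighbor deduplicated
  expect_identical(ns$down_genes, "gB")     # l4 has no neighbor
  expect_identical(ns$universe_genes, c("gA", "gB"))
  expect_warning(res <- fisher_enrichment(character(0),
                                          toy_collection(list(S = "gA"),
                                                         c("gA", "gB"))),
                 "empty query")
  expect_equal(nrow(res), 0)
})

test_that("the planted cardiac set attains the minimum enrichment p-value", {
  # study-scale annotation and gene sets, DE lncRNAs selected the way the
  # bundle generator selects them (candidates + extras, half of the extras'
  # neighbors carrying the cardiac annotation)
  hits <- 0L
  n_runs <- 20L
  for (s in seq_len(n_runs)) {
    cfg <- sim_config(seed = s)
    ann <- generate_annotation(cfg)
    cls <- classify_lncrnas(ann$annotation)
    truth_cls <- ann$truth$class_by_lncrna
    candidates <- c(names(truth_cls)[truth_cls == "natural_antisense"][1],
                    names(truth_cls)[truth_cls == "bidirectional"][1])
    set.seed(s)
    extra <- sample(setdiff(names(truth_cls), candidates),
                    max(2, round(cfg$fraction_de * length(truth_cls))) - 2)
    de_lnc <- c(candidates, extra)
    in_cardiac <- extra[seq_len(length(extra) %/% 2)]
    cardiac <- unname(ann$truth$neighbor_by_lncrna[c(candidates, in_cardiac)])
    avoid <- unname(ann$truth$neighbor_by_lncrna[setdiff(extra, in_cardiac)])
    gs <- generate_gene_sets(cfg, ann$annotation, cardiac_genes = cardiac,
                             avoid_genes = avoid)
    ns <- neighbor_gene_sets(cls, de_lnc, character(0))
    coll <- gene_set_collection(gs$sets, ns$universe_genes)
    res <- fisher_enrichment(ns$up_genes, coll)
    if (res$set_id[1] == "CARDIAC_DEV") hits <- hits + 1L
  }
  expect_gte(hits / n_runs, 0.95)
})

test_that("adding a query gene outside every set never lowers any p-value", {
  set.seed(6)
  universe <- paste0("g", 1:50)
  sets <- list(A = paste0("g", 1:10), B = paste0("g", 20:35))
  coll <- toy_collection(sets, universe)
  q <- paste0("g", c(2, 3, 25))
  before <- fisher_enrichment(q, coll)
  after <- fisher_enrichment(c(q, "g49"), coll)  # g49 in no set
  after <- after[match(before$set_id, after$set_id), ]
  expect_true(all(after$p_value >= before$p_value - 1e-15))
})
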