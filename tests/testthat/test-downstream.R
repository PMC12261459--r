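# --- helpers ---------------------------------------------------------------

traj_matrix <- function(n_genes, t = seq(0, 1440, by = 10), seed = 1,
                        common = NULL, noise = 1) {
  set.seed(seed)
  m <- t(vapply(seq_len(n_genes), function(i) {
    base <- if (is.null(common)) rep(0, length(t)) else common
    base + noise * cumsum(rnorm(length(t), 0, 0.1))
  }, numeric(length(t))))
  rownames(m) <- sprintf("g%03d", seq_len(n_genes))
  m
}

make_annotation <- function(ids, chrom = "chr1", start0 = 1e5, gap = 2e4) {
  data.frame(gene_id = ids, chromosome = chrom,
             start = start0 + (seq_along(ids) - 1) * gap,
             end = start0 + (seq_along(ids) - 1) * gap + 5e3,
             strand = "+")
}

# a dense mean_trajectory object as classify_buffered consumes it
buffering_fixture <- function(gene_id, alpha, gamma, U, S,
                              t = seq(0, 1440, by = 1)) {
  structure(list(gene_id = gene_id,
                 mean_trajectory = data.frame(
                   time = t, U_fit = U(t), S_fit = S(t),
                   alpha = alpha(t), beta = rep(0.2, length(t)),
                   gamma = gamma(t))),
            class = "trained_gene_model")
}

# smooth step used by the buffering fixtures
stp <- function(t, t0 = 300, w = 40) 1 / (1 + exp(-(t - t0) / w))

# --- cross-correlation matrix ---------------------------------------------

test_that("genomic cross-correlation matrices are symmetric with unit diagonal", {
  m <- traj_matrix(5)
  ann <- make_annotation(rownames(m))
  cc <- cc_matrix(m, ann)
  expect_identical(cc, t(cc))
  expect_equal(unname(diag(cc)), rep(1, 5))
  # two identical trajectories correlate at exactly 1
  m2 <- m
  m2["g002", ] <- m2["g001", ]
  cc2 <- cc_matrix(m2, ann)
  expect_equal(cc2["g001", "g002"], 1)
  # a constant trajectory gets flagged-missing row and column
  m3 <- m
  m3["g003", ] <- 2
  cc3 <- cc_matrix(m3, ann)
  expect_true(all(is.na(cc3["g003", ])) && all(is.na(cc3[, "g003"])))
  expect_equal(cc3["g001", "g001"], 1)
})

test_that("a planted synchronized pair dominates the off-diagonal entries", {
  t <- seq(0, 1440, by = 10)
  common <- sin(2 * pi * t / 720)
  m <- traj_matrix(3, t, seed = 3)
  m["g001", ] <- common + 0.05 * rnorm(length(t))
  m["g002", ] <- common + 0.05 * rnorm(length(t))
  ann <- make_annotation(rownames(m))
  cc <- cc_matrix(m, ann, region = c("chr1", 0, 1e6))
  off <- cc
  diag(off) <- -Inf
  expect_equal(which(off == max(off), arr.ind = TRUE)[1, ],
               c(row = 2, col = 1), ignore_attr = TRUE)
  # genes are ordered by genomic start position
  expect_equal(rownames(cc), ann$gene_id[order(ann$start)])
})

# --- enhancer proximity -----------------------------------------------------

test_that("enhancer distances, bins and the activity threshold behave as specified", {
  m <- traj_matrix(6)
  ann <- make_annotation(rownames(m), start0 = 1e5, gap = 6e4)
  enh <- data.frame(chromosome = "chr1", start = 1.02e5, end = 1.03e5,
                    total_tpm = exp(5) - 1)  # log(tpm+1) = 5 > 4: active
  res <- enhancer_proximity_synchrony(m, ann, enh, test_pairs = list())
  # the overlapping gene has distance 0 and bin 0
  expect_equal(res$gene_stats$distance[res$gene_stats$gene_id == "g001"], 0)
  expect_equal(res$gene_stats$bin[res$gene_stats$gene_id == "g001"], 0)
  # the farthest gene (300 kb away) lands in the bin 50 kb binning implies
  g6 <- res$gene_stats[res$gene_stats$gene_id == "g006", ]
  expect_equal(g6$bin, floor(g6$distance / 50000))
  # a threshold above every locus leaves no active enhancer
  enh$total_tpm <- 1
  expect_error(enhancer_proximity_synchrony(m, ann, enh), "threshold")
})

test_that("synchrony planted near active enhancers is detected (positive control)", {
  t <- seq(0, 1440, by = 10)
  common <- sin(2 * pi * t / 720)
  n_near <- 50
  n_far <- 50
  set.seed(9)
  near <- t(vapply(seq_len(n_near), function(i)
    common + rnorm(length(t), 0, 0.35), numeric(length(t))))
  far <- t(vapply(seq_len(n_far), function(i)
    cumsum(rnorm(length(t), 0, 0.1)), numeric(length(t))))
  m <- rbind(near, far)
  rownames(m) <- sprintf("g%03d", seq_len(n_near + n_far))
  # near genes within 50 kb of the enhancer (bin 0); all far genes in one
  # distant bin so both groups hold 50 genes
  ann <- data.frame(
    gene_id = rownames(m), chromosome = "chr2",
    start = c(seq(1.0e5, 1.4e5, length.out = n_near),
              seq(6.01e5, 6.4e5, length.out = n_far)),
    stringsAsFactors = FALSE)
  ann$start <- round(ann$start)
  ann$end <- ann$start + 1000
  enh <- data.frame(chromosome = "chr2", start = 99000, end = 100000,
                    total_tpm = exp(6))
  res <- enhancer_proximity_synchrony(m, ann, enh)
  expect_gt(res$bin_summary$mean_avg_cc[res$bin_summary$bin == 0],
            max(res$bin_summary$mean_avg_cc[res$bin_summary$bin > 0]))
  far_bin <- max(res$gene_stats$bin)
  expect_equal(sum(res$gene_stats$bin == far_bin), n_far)
  sig <- res$tests[res$tests$bin_b == far_bin, ]
  expect_lt(sig$p_adj, 0.05)
})

# --- dynamic buffering ------------------------------------------------------

test_that("the buffering rule classifies each clause-toggled fixture as designed", {
  # base (buffered): alpha and gamma double together; U rises, S stays flat
  base <- buffering_fixture(
    "buffered",
    alpha = function(t) 1 + stp(t), gamma = function(t) 0.02 * (1 + stp(t)),
    U = function(t) 1 + stp(t), S = function(t) rep(50, length(t)))
  call <- classify_buffered(base)
  expect_true(call$buffered)
  expect_equal(call$direction, "up")
  expect_gt(call$cc_alpha_gamma, 0.99)

  # toggle 1: spliced dynamics vary more than unspliced -> not buffered
  t1 <- buffering_fixture(
    "sd_violated",
    alpha = function(t) 1 + stp(t), gamma = function(t) 0.02 * (1 + stp(t)),
    U = function(t) rep(1, length(t)), S = function(t) 50 * (1 + stp(t)))
  expect_false(classify_buffered(t1)$buffered)

  # toggle 2: degradation anti-correlated with transcription -> not buffered
  t2 <- buffering_fixture(
    "anticorrelated",
    alpha = function(t) 1 + stp(t), gamma = function(t) 0.02 * (2 - stp(t)),
    U = function(t) 1 + stp(t), S = function(t) rep(50, length(t)))
  call2 <- classify_buffered(t2)
  expect_false(call2$buffered)
  expect_lt(call2$cc_alpha_gamma, -0.9)

  # toggle 3: gamma follows alpha only after 120 min (outside the 60-min lag
  # window); narrow bumps keep the windowed correlation low -> not buffered
  bump <- function(t, tc) exp(-((t - tc) / 25)^2)
  t3 <- buffering_fixture(
    "lagged",
    alpha = function(t) 1 + bump(t, 300),
    gamma = function(t) 0.02 * (1 + bump(t, 420)),
    U = function(t) 1 + bump(t, 300), S = function(t) rep(50, length(t)))
  call3 <- classify_buffered(t3)
  expect_false(call3$buffered)
  expect_lt(call3$cc_alpha_gamma, 0.75)

  # direction: transcription falling within the first hour -> "down"
  t4 <- buffering_fixture(
    "down",
    alpha = function(t) 2 - stp(t, t0 = 30, w = 10),
    gamma = function(t) 0.02 * (2 - stp(t, t0 = 30, w = 10)),
    U = function(t) 2 - stp(t, t0 = 30, w = 10),
    S = function(t) rep(50, length(t)))
  call4 <- classify_buffered(t4)
  expect_true(call4$buffered)
  expect_equal(call4$direction, "down")

  # constant transcription: coupling undefined -> not buffered
  t5 <- buffering_fixture(
    "flat",
    alpha = function(t) rep(1, length(t)), gamma = function(t) rep(0.02, length(t)),
    U = function(t) 1 + stp(t), S = function(t) rep(50, length(t)))
  expect_false(classify_buffered(t5)$buffered)
  # equal dynamics SDs fail the strict inequality
  t6 <- buffering_fixture(
    "tie",
    alpha = function(t) 1 + stp(t), gamma = function(t) 0.02 * (1 + stp(t)),
    U = function(t) 1 + stp(t), S = function(t) 1 + stp(t))
  expect_false(classify_buffered(t6)$buffered)
})

test_that("condition-specific set logic is exact", {
  mk <- function(ids, buffered) data.frame(gene_id = ids, buffered = buffered)
  u <- letters[1:6]
  a <- mk(u, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  b <- mk(u, c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE))
  r <- condition_specific_sets(a, b)
  expect_equal(sort(r$a_specific), c("b", "c"))
  expect_equal(r$b_specific, "d")
  expect_equal(condition_specific_sets(a, a),
               list(a_specific = character(0), b_specific = character(0)))
  # A superset of B: A-specific is the set difference
  b2 <- mk(u, c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(condition_specific_sets(a, b2)$a_specific, "c")
  expect_error(condition_specific_sets(a, mk(letters[2:7], rep(TRUE, 6))),
               "universe")
})

# --- RBP enrichment ---------------------------------------------------------

# Independent oracle: two-sided Fisher exact p by brute-force enumeration of
# the hypergeometric distribution over all tables with the observed margins.
fisher_p_bruteforce <- function(a, b, c_, d) {
  r1 <- a + b
  c1 <- a + c_
  n <- a + b + c_ + d
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(ks, r1, n - r1, c1)
  p_obs <- stats::dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

test_that("RBP enrichment reproduces exact-test facts on canonical tables", {
  universe <- sprintf("g%02d", 1:40)
  # symmetric table (10,10,10,10): OR 1, p = 1
  group <- universe[1:20]
  targets <- list(rbp1 = universe[c(1:10, 21:30)])
  r <- rbp_enrichment(group, universe, targets)
  expect_equal(r$odds_ratio, 1)
  expect_equal(r$p, 1)
  # table (8,2,2,8): cross-product odds ratio 16, p from the exact tail sum
  group2 <- universe[1:10]
  targets2 <- list(rbp1 = universe[c(1:8, 11:12)])
  r2 <- rbp_enrichment(group2, universe[1:20], targets2)
  expect_equal(r2$a, 8)
  expect_equal(r2$odds_ratio, 16)
  expect_equal(r2$p, fisher_p_bruteforce(8, 2, 2, 8))
  expect_error(rbp_enrichment(character(0), universe, targets), "empty")
})

test_that("Fisher p-values agree with brute-force hypergeometric enumeration", {
  # exhaustive over all tables with margins <= 8
  for (r1 in 0:8) for (c1 in 0:8) {
    n <- 12
    for (a in max(0, r1 + c1 - n):min(r1, c1)) {
      b <- r1 - a
      c_ <- c1 - a
      d <- n - a - b - c_
      p_pkg <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))$p.value
      expect_equal(p_pkg, fisher_p_bruteforce(a, b, c_, d), tolerance = 1e-9)
    }
  }
  # random tables with margins up to 30
  set.seed(7)
  for (i in 1:200) {
    a <- sample(0:15, 1); b <- sample(0:15, 1)
    c_ <- sample(0:15, 1); d <- sample(0:15, 1)
    p_pkg <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))$p.value
    expect_equal(p_pkg, fisher_p_bruteforce(a, b, c_, d), tolerance = 1e-9)
  }
})

test_that("BH adjustment matches the textbook step-up procedure", {
  bh_textbook <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    out <- numeric(m)
    out[o] <- pmin(adj, 1)
    out
  }
  set.seed(12)
  for (i in 1:2000) {
    p <- runif(sample(2:25, 1))
    expect_equal(stats::p.adjust(p, "BH"), bh_textbook(p), tolerance = 1e-12)
  }
  # equal p-values keep their common value under BH
  r <- rbp_enrichment(letters[1:5], letters[1:20],
                      list(r1 = letters[c(1, 6:9)], r2 = letters[c(2, 10:13)]))
  expect_equal(r$p_adj, r$p)  # identical tables -> identical (tied) p-values
})

test_that("enrichment output is ranked by odds ratio and flags significance", {
  set.seed(5)
  universe <- sprintf("g%03d", 1:200)
  group <- universe[1:50]
  targets <- list(
    strong = c(universe[1:40], universe[51:60]),   # heavily enriched
    none = sample(universe, 50),                   # ~random
    depleted = universe[51:100]                    # absent from the group
  )
  r <- rbp_enrichment(group, universe, targets,
                      expressed_rbps = c("strong", "none", "depleted"))
  expect_equal(r$rbp[1], "strong")
  expect_true(r$significant[r$rbp == "strong"])
  expect_true(r$significant[r$rbp == "depleted"])  # two-sided: depletion too
  expect_equal(nrow(r), 3)
})
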