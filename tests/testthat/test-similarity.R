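test_that("histogram pdfs follow Scott's rule and always sum to 1", {
  x <- with_seed_test(81, rnorm(1000))
  P <- pdf_histogram(x)
  h <- diff(P$edges)[1]
  expect_equal(h, 3.49 * stats::sd(x) * 1000^(-1 / 3), tolerance = 1e-12)
  expect_equal(sum(P$probs), 1, tolerance = 1e-12)
  expect_true(all(P$probs >= 0))
  # supplied edges are reused verbatim
  Q <- pdf_histogram(with_seed_test(82, rnorm(500)), edges = P$edges)
  expect_identical(Q$edges, P$edges)
  expect_equal(sum(Q$probs), 1, tolerance = 1e-12)
  expect_warning(pdf_histogram(rep(1, 50)), "zero-variance")
  expect_error(pdf_histogram(numeric(0)), "empty")
  expect_error(pdf_histogram(rnorm(10), edges = c(0, 0)), "increasing")
})

test_that("self-similarity attains each measure's analytic value", {
  P <- pdf_histogram(with_seed_test(83, rnorm(2000)))
  rep_ <- similarity_suite(P, P)
  m <- rep_$measures
  # distances vanish on identical pdfs, so s = 1 - d = 1; similarity-native
  # measures reach their analytic self-values: 1 for all but Motyka (whose
  # maximum is 1/2) and the raw inner product (sum of squared masses)
  for (i in seq_len(nrow(m))) {
    expected <- switch(m$measure[i],
                       Motyka = 0.5,
                       InnerProduct = sum(P$probs^2),
                       1)
    expect_equal(m$similarity[i], expected, tolerance = 1e-12,
                 label = m$measure[i])
  }
  expect_equal(rep_$kld, 0)
  expect_equal(rep_$correlation, 1)
})

test_that("s = 1 - d exactly for every distance-derived measure", {
  P <- pdf_histogram(with_seed_test(84, rnorm(800)))
  Q <- pdf_histogram(with_seed_test(85, rnorm(800, 0.4, 1.4)),
                     edges = P$edges)
  m <- similarity_suite(P, Q)$measures
  d <- m$distance[!is.na(m$distance)]
  s <- m$similarity[!is.na(m$distance)]
  expect_identical(s, 1 - d)
})

test_that("disjoint supports zero out intersection and fidelity", {
  P <- structure(list(edges = c(0, 1, 2), probs = c(1, 0)), class = "tf_pdf")
  Q <- structure(list(edges = c(0, 1, 2), probs = c(0, 1)), class = "tf_pdf")
  m <- similarity_suite(P, Q)$measures
  expect_equal(m$similarity[m$measure == "Intersection"], 0)
  expect_equal(m$similarity[m$measure == "Fidelity"], 0)
})

test_that("two-bin hand-computed examples match", {
  P <- structure(list(edges = c(0, 0.5, 1), probs = c(0.5, 0.5)),
                 class = "tf_pdf")
  Q <- structure(list(edges = c(0, 0.5, 1), probs = c(0.9, 0.1)),
                 class = "tf_pdf")
  m <- suppressWarnings(similarity_suite(P, Q))$measures  # 2-bin pdfs have
  # constant probability vectors, so the appended correlation warns
  g <- function(nm, col = "similarity") m[[col]][m$measure == nm]
  expect_equal(g("Euclidean", "distance"), sqrt(2 * 0.4^2), tolerance = 1e-12)
  expect_equal(g("Euclidean"), 1 - sqrt(0.32), tolerance = 1e-12)
  expect_equal(g("Chebyshev", "distance"), 0.4, tolerance = 1e-12)
  expect_equal(g("Sorensen", "distance"), 0.8 / 2, tolerance = 1e-12)
  expect_equal(g("Intersection"), 0.5 + 0.1, tolerance = 1e-12)
  expect_equal(g("InnerProduct"), 0.5 * 0.9 + 0.5 * 0.1, tolerance = 1e-12)
  expect_equal(g("Fidelity"), sqrt(0.45) + sqrt(0.05), tolerance = 1e-12)
  expect_equal(g("SquaredEuclidean", "distance"), 0.32, tolerance = 1e-12)
  # KLD closed form: P = (1, 0) vs Q = (0.5, 0.5) gives ln 2
  P1 <- structure(list(edges = c(0, 0.5, 1), probs = c(1, 0)),
                  class = "tf_pdf")
  Qh <- structure(list(edges = c(0, 0.5, 1), probs = c(0.5, 0.5)),
                  class = "tf_pdf")
  expect_equal(kld(P1, Qh), log(2), tolerance = 1e-12)
})

test_that("KLD is non-negative, zero on identity, and edge-checked", {
  P <- pdf_histogram(with_seed_test(86, rnorm(400)))
  expect_equal(kld(P, P), 0)
  for (seed in 87:96) {
    nb <- 12
    p <- with_seed_test(seed, {x <- runif(nb); x / sum(x)})
    q <- with_seed_test(seed + 100, {x <- runif(nb); x / sum(x)})
    Pp <- structure(list(edges = 0:nb, probs = p), class = "tf_pdf")
    Qq <- structure(list(edges = 0:nb, probs = q), class = "tf_pdf")
    expect_gte(kld(Pp, Qq), 0)
  }
  Q2 <- pdf_histogram(rnorm(400), edges = P$edges + 0.1)
  expect_error(kld(P, Q2), "different bin grids")
  expect_error(similarity_suite(P, Q2), "different bin grids")
})

test_that("pdf correlation behaves like Pearson's r", {
  p <- c(0.05, 0.1, 0.2, 0.3, 0.2, 0.1, 0.05)
  P <- structure(list(edges = 0:7, probs = p), class = "tf_pdf")
  expect_equal(pdf_correlation(P, P), 1)
  skew <- c(0.4, 0.25, 0.15, 0.1, 0.05, 0.03, 0.02)
  Ps <- structure(list(edges = 0:7, probs = skew), class = "tf_pdf")
  Pr <- structure(list(edges = 0:7, probs = rev(skew)), class = "tf_pdf")
  expect_lt(pdf_correlation(Ps, Pr), 0)
  flat <- structure(list(edges = 0:7, probs = rep(1 / 7, 7)),
                    class = "tf_pdf")
  expect_warning(r0 <- pdf_correlation(flat, P), "constant")
  expect_equal(r0, 0)
})

test_that("similarity to the clean reference rises with SNR while KLD falls", {
  cl <- fix_utterance()
  nz <- fix_noise()
  cut <- with_seed_test(5, random_cut(nz, length(cl$samples)))
  ref_voc <- vocode(cl)
  ref_pdf <- pdf_histogram(ref_voc)
  fams <- sapply(c(-5, 5), function(s) {
    mixv <- vocode(mix_at_snr(cl, cut, s)$mixture)
    r <- similarity_suite(ref_pdf, pdf_histogram(mixv, edges = ref_pdf$edges))
    c(fid = r$families[["Fidelity"]], kld = r$kld, rho = r$correlation)
  })
  expect_gt(fams["fid", 2], fams["fid", 1])
  expect_lt(fams["kld", 2], fams["kld", 1])
  expect_gt(fams["rho", 2], fams["rho", 1])
})
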