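#' Histogram probability distribution of a signal
#'
#' Bins a signal's amplitude values into a normalized histogram. When no
#' edges are supplied the bin width follows Scott's rule,
#' `h = 3.49 * sd(x) * n^(-1/3)`; supplying the edges of a reference pdf
#' puts two signals on a common grid, which the similarity battery
#' requires. Values are assigned to left-closed bins; the outermost edges
#' are stretched to cover the data when edges are auto-computed, and values
#' outside supplied edges fall into the end bins so the masses still sum
#' to 1.
#'
#' @param x a [waveform] or numeric vector.
#' @param edges optional bin edges (increasing numeric vector) to reuse.
#' @return An object of class `"tf_pdf"`: list with `edges` and `probs`
#'   (summing to 1).
#' @export
pdf_histogram <- function(x, edges = NULL) {
  if (inherits(x, "waveform")) x <- x$samples
  x <- as.numeric(x)
  if (length(x) == 0) stop("empty signal")
  if (is.null(edges)) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      warning("zero-variance signal: single-bin pdf")
      edges <- c(min(x) - 0.5, max(x) + 0.5)
    } else {
      h <- 3.49 * s * length(x)^(-1 / 3)
      nb <- max(1L, ceiling((max(x) - min(x)) / h))
      edges <- seq(min(x), min(x) + nb * h, length.out = nb + 1L)
    }
  }
  if (any(diff(edges) <= 0)) stop("'edges' must be strictly increasing")
  cnt <- bin_counts(x, edges)
  structure(list(edges = edges, probs = cnt / length(x)), class = "tf_pdf")
}

# left-closed bins [e_k, e_{k+1}); out-of-range values clamped to end bins
bin_counts <- function(x, edges) {
  k <- findInterval(x, edges, rightmost.closed = TRUE)
  k <- pmin(pmax(k, 1L), length(edges) - 1L)
  tabulate(k, nbins = length(edges) - 1L)
}

#' @export
print.tf_pdf <- function(x, ...) {
  cat(sprintf("<tf_pdf> %d bins on [%.4g, %.4g], mass %.6f\n",
              length(x$probs), x$edges[1], x$edges[length(x$edges)],
              sum(x$probs)))
  invisible(x)
}

check_same_edges <- function(P, Q) {
  stopifnot(inherits(P, "tf_pdf"), inherits(Q, "tf_pdf"))
  if (length(P$edges) != length(Q$edges) ||
      max(abs(P$edges - Q$edges)) > 1e-12)
    stop("pdfs are on different bin grids; rebuild Q with P's edges")
  invisible(TRUE)
}

#' Kullback-Leibler divergence between binned pdfs
#'
#' `sum(P_i * log(P_i / Q_i))` with `P_i = 0` terms contributing 0 and
#' `Q_i` floored at 1e-12 where `P_i > 0` (avoiding `0 * log 0` and
#' division by zero). Non-negative; 0 iff the pdfs coincide.
#'
#' @param P,Q `"tf_pdf"` objects on identical edges.
#' @return A single non-negative number (nats).
#' @export
kld <- function(P, Q) {
  check_same_edges(P, Q)
  p <- P$probs; q <- Q$probs
  i <- p > 0
  sum(p[i] * log(p[i] / pmax(q[i], 1e-12)))
}

#' Pearson correlation between two binned pdfs
#'
#' @inheritParams kld
#' @return Correlation in \[-1, 1\]; 0 (with a warning) when either
#'   probability vector is constant.
#' @export
pdf_correlation <- function(P, Q) {
  check_same_edges(P, Q)
  if (stats::sd(P$probs) == 0 || stats::sd(Q$probs) == 0) {
    warning("constant probability vector: correlation undefined, returning 0")
    return(0)
  }
  stats::cor(P$probs, Q$probs)
}

# individual similarity measures, following Cha's taxonomy; each returns the
# distance d (NA when similarity-native) and similarity s
similarity_measures <- function(p, q, eps = 1e-12) {
  ad <- abs(p - q); mn <- pmin(p, q); mx <- pmax(p, q)
  pq <- p * q; sp2 <- sum(p^2); sq2 <- sum(q^2); spq <- sum(pq)
  fid <- sum(sqrt(pq))
  wh_terms <- ifelse(mx > 0, ad / mx, 0)
  tan_arg <- ifelse(p + q > 0, (p + q) / (2 * pmax(sqrt(pq), eps)), 1)
  rows <- list(
    list("Euclidean",        "Lp",            d = sqrt(sum(ad^2))),
    list("Chebyshev",        "Lp",            d = max(ad)),
    list("Sorensen",         "L1",            d = sum(ad) / sum(p + q)),
    list("Gower",            "L1",            d = mean(ad)),
    list("Soergel",          "L1",            d = sum(ad) / max(sum(mx), eps)),
    list("Intersection",     "Intersection",  s = sum(mn)),
    list("WaveHedges",       "Intersection",  d = sum(wh_terms)),
    list("Czekanowski",      "Intersection",  s = 2 * sum(mn) / sum(p + q)),
    list("Motyka",           "Intersection",  s = sum(mn) / sum(p + q)),
    list("Ruzicka",          "Intersection",  s = sum(mn) / max(sum(mx), eps)),
    list("Tanimoto",         "Intersection",
         d = (sum(mx) - sum(mn)) / max(sum(mx), eps)),
    list("InnerProduct",     "InnerProduct",  s = spq),
    list("Cosine",           "InnerProduct",
         s = spq / max(sqrt(sp2 * sq2), eps)),
    list("KumarHassebrook",  "InnerProduct",
         s = spq / max(sp2 + sq2 - spq, eps)),
    list("Dice",             "InnerProduct",
         s = 2 * spq / max(sp2 + sq2, eps)),
    list("Fidelity",         "Fidelity",      s = fid),
    list("Bhattacharyya",    "Fidelity",      d = -log(max(fid, eps))),
    list("Matusita",         "Fidelity",      d = sqrt(sum((sqrt(p) - sqrt(q))^2))),
    list("SquaredChord",     "Fidelity",      d = sum((sqrt(p) - sqrt(q))^2)),
    list("SquaredEuclidean", "SquaredL2",     d = sum(ad^2)),
    list("Taneja",           "Combinations",
         d = sum(((p + q) / 2) * log(tan_arg))),
    list("Average",          "Combinations",  d = (sum(ad) + max(ad)) / 2)
  )
  do.call(rbind, lapply(rows, function(r) {
    d <- if (!is.null(r$d)) r$d else NA_real_
    s <- if (!is.null(r$s)) r$s else 1 - d
    data.frame(measure = r[[1]], family = r[[2]], distance = d,
               similarity = s, stringsAsFactors = FALSE)
  }))
}

#' Similarity battery between two binned pdfs
#'
#' Computes the full eight-family similarity/divergence battery on a pair of
#' pdfs sharing a bin grid: the Lp Minkowski family (Euclidean, Chebyshev),
#' the L1 family (Sorensen, Gower, Soergel), the Intersection family
#' (Intersection, Wave Hedges, Czekanowski, Motyka, Ruzicka, Tanimoto), the
#' Inner Product family (Inner Product, Cosine, Kumar-Hassebrook, Dice), the
#' Fidelity family (Fidelity, Bhattacharyya, Matusita, Squared Chord),
#' Squared L2 (Squared Euclidean), the Combinations family (Taneja,
#' Average), and Shannon's Entropy (Kullback-Leibler divergence). Distances
#' `d` are converted to similarities by `s = 1 - d`; the Shannon's Entropy
#' family is reported as the raw divergence (smaller = more similar). The
#' Pearson correlation between the probability vectors is appended.
#'
#' @inheritParams kld
#' @param aggregate how to collapse each family's members into the family
#'   score: `"mean"` (arithmetic mean of member similarities; the default)
#'   or `"none"` to skip aggregation.
#' @return An object of class `"similarity_report"`: list with `measures`
#'   (per-measure data.frame), `families` (named family scores, including
#'   `ShannonEntropy` = KLD and `Correlation`), and `correlation`.
#' @export
similarity_suite <- function(P, Q, aggregate = c("mean", "none")) {
  aggregate <- match.arg(aggregate)
  check_same_edges(P, Q)
  meas <- similarity_measures(P$probs, Q$probs)
  dkl <- kld(P, Q)
  rho <- pdf_correlation(P, Q)
  fam <- NULL
  if (aggregate == "mean") {
    fam <- vapply(split(meas$similarity, meas$family), mean, numeric(1))
    fam <- fam[c("Lp", "L1", "Intersection", "InnerProduct", "Fidelity",
                 "SquaredL2", "Combinations")]
    fam <- c(fam, ShannonEntropy = dkl, Correlation = rho)
  }
  structure(list(measures = meas, families = fam, kld = dkl,
                 correlation = rho),
            class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat("<similarity_report>\n")
  if (!is.null(x$families)) {
    for (nm in names(x$families))
      cat(sprintf("  %-15s %8.4f\n", nm, x$families[[nm]]))
  } else {
    print(x$measures)
  }
  invisible(x)
}
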