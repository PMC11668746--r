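# Independent oracles: deliberately naive, loop-based implementations that
# share no code path with the package.

# Clopper-Pearson bounds by direct bisection of the binomial tail sums,
# never touching beta quantiles
cp_bisect_oracle <- function(x, n, conf.level = 0.95, tol = 1e-12) {
  alpha <- 1 - conf.level
  bisect <- function(f, lo, hi) {
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
      if (hi - lo < tol) break
    }
    (lo + hi) / 2
  }
  lower <- if (x == 0) 0 else {
    # smallest p with P(X >= x | p) = alpha/2 ; tail is increasing in p
    bisect(function(p) sum(dbinom(x:n, n, p)) - alpha / 2, 0, 1)
  }
  upper <- if (x == n) 1 else {
    # P(X <= x | p) = alpha/2 ; this tail is decreasing in p
    bisect(function(p) alpha / 2 - sum(dbinom(0:x, n, p)), 0, 1)
  }
  c(lower, upper)
}

# position-by-position degenerate-site matcher over an IUPAC table
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

naive_cut_sites <- function(seq, recognition, cut_offset) {
  s <- strsplit(seq, "")[[1]]
  p <- strsplit(recognition, "")[[1]]
  w <- length(p)
  cuts <- integer(0)
  for (i in seq_len(length(s) - w + 1L)) {
    ok <- TRUE
    for (j in seq_len(w)) {
      if (!(s[i + j - 1L] %in% IUPAC_SETS[[p[j]]])) { ok <- FALSE; break }
    }
    if (ok) cuts <- c(cuts, i - 1L + cut_offset)
  }
  cuts <- sort(unique(cuts))
  cuts[cuts > 0L & cuts < length(s)]
}

# exhaustive ROH oracle: checks every window with explicit loops, unions
# covered markers, trims to homozygous ends, filters
roh_oracle <- function(pos, call, params) {
  m <- length(call)
  w <- params$window_markers
  if (m < w) return(data.frame(start_bp = integer(), end_bp = integer()))
  covered <- rep(FALSE, m)
  for (i in seq_len(m - w + 1L)) {
    win <- call[i:(i + w - 1L)]
    if (sum(win == "HET") <= params$max_het_per_window &&
        sum(win == "MISSING") <= params$max_missing_per_window) {
      covered[i:(i + w - 1L)] <- TRUE
    }
  }
  segs <- data.frame(start_bp = integer(), end_bp = integer(),
                     n_markers = integer())
  i <- 1L
  while (i <= m) {
    if (covered[i]) {
      j <- i
      while (j < m && covered[j + 1L]) j <- j + 1L
      idx <- i:j
      hom <- idx[call[idx] %in% c("HOM_REF", "HOM_ALT")]
      if (length(hom)) {
        a <- min(hom); b <- max(hom)
        if (pos[b] - pos[a] + 1L >= params$min_length_bp &&
            b - a + 1L >= params$min_markers) {
          segs <- rbind(segs, data.frame(
            start_bp = pos[a], end_bp = pos[b], n_markers = b - a + 1L
          ))
        }
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  segs
}

# linear interpolation by explicit flanking-knot arithmetic (the "dense
# grid" rule evaluated directly at the query)
interp_oracle <- function(bp_knots, cm_knots, q) {
  vapply(q, function(x) {
    if (x <= bp_knots[1]) return(cm_knots[1])
    k <- length(bp_knots)
    if (x >= bp_knots[k]) return(cm_knots[k])
    i <- max(which(bp_knots <= x))
    if (bp_knots[i] == x) return(cm_knots[i])
    cm_knots[i] + (cm_knots[i + 1] - cm_knots[i]) *
      (x - bp_knots[i]) / (bp_knots[i + 1] - bp_knots[i])
  }, numeric(1))
}

# gamma quantile by numerical integration of the density + root search,
# independent of qgamma
gamma_quantile_oracle <- function(p, shape) {
  cdf <- function(q) {
    integrate(function(t) t^(shape - 1) * exp(-t) / gamma(shape),
              0, q, rel.tol = 1e-12)$value
  }
  uniroot(function(q) cdf(q) - p, c(1e-12, shape * 20), tol = 1e-10)$root
}

# random genotype track with planted homozygous stretches, for oracle
# equivalence tests
random_genotype_track <- function(m, seed) {
  set.seed(seed)
  pos <- sort(sample.int(m * 2000L, m))
  call <- sample(c("HOM_REF", "HOM_ALT", "HET", "MISSING"), m,
                 replace = TRUE, prob = c(0.45, 0.25, 0.2, 0.1))
  # plant 1-3 homozygous stretches so segments exist sometimes
  for (k in seq_len(sample(1:3, 1))) {
    a <- sample.int(m - 60L, 1)
    len <- sample(40:180, 1)
    b <- min(m, a + len)
    call[a:b] <- sample(c("HOM_REF", "HOM_ALT"), b - a + 1L, replace = TRUE)
  }
  list(pos = pos, call = call)
}
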