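# Orthogonal wavelet machinery: periodized two-channel filter bank
# (Mallat cascade), full wavelet-packet tree, Gray-code frequency
# ordering, and band reconstruction.

# Daubechies db5 analysis filters (10 taps, 5 vanishing moments).
# Standard published values; synthesis uses the adjoint of the analysis
# operator, which for an orthogonal periodized transform is exact.
DB5_DEC_LO <- c(
   0.003335725285473771, -0.012580751999081999, -0.006241490212798274,
   0.077571493840045720, -0.032244869584638375, -0.242294887066382030,
   0.138428145901320740,  0.724308528437772900,  0.603829269797189600,
   0.160102397974192930)
DB5_DEC_HI <- c(
  -0.160102397974192930,  0.603829269797189600, -0.724308528437772900,
   0.138428145901320740,  0.242294887066382030, -0.032244869584638375,
  -0.077571493840045720, -0.006241490212798274,  0.012580751999081999,
   0.003335725285473771)

#' Wavelet specification
#'
#' Bundles the analysis/synthesis filter coefficients and decomposition
#' depth used by the packet transform. The built-in family is `db5`
#' (Daubechies, 5 vanishing moments, 10-tap filters), the wavelet used
#' throughout this package for EEG rhythm extraction. Custom orthogonal
#' filters may be supplied through `dec_lo`/`dec_hi` as an escape hatch.
#'
#' @param name Wavelet family name. Only `"db5"` is built in.
#' @param levels Decomposition depth (default 4, giving 16 subbands of
#'   width `fs/2/2^4` Hz).
#' @param dec_lo,dec_hi Optional custom analysis low/high-pass filters
#'   (must form an orthogonal pair; checked via perfect reconstruction
#'   in the test-suite, not here).
#' @return An object of class `wavelet_spec` with fields `name`,
#'   `dec_lo`, `dec_hi`, `rec_lo`, `rec_hi`, `levels`.
#' @examples
#' spec <- wavelet_spec()
#' length(spec$dec_lo) # 10 taps
#' @export
wavelet_spec <- function(name = "db5", levels = 4L,
                         dec_lo = NULL, dec_hi = NULL) {
  if (is.null(dec_lo)) {
    if (!identical(name, "db5")) {
      stop("only the 'db5' wavelet is built in; supply dec_lo/dec_hi for ",
           "other orthogonal filters", call. = FALSE)
    }
    dec_lo <- DB5_DEC_LO
    dec_hi <- DB5_DEC_HI
  } else {
    if (is.null(dec_hi)) {
      L <- length(dec_lo)
      dec_hi <- rev(dec_lo) * (-1)^(seq_len(L) - 1L) # QMF partner
    }
    stopifnot(length(dec_lo) == length(dec_hi))
  }
  levels <- as.integer(levels)
  if (levels < 1L) stop("levels must be >= 1", call. = FALSE)
  structure(
    list(name = name,
         dec_lo = dec_lo, dec_hi = dec_hi,
         # time-reversed filters: the convolution form of the adjoint
         rec_lo = rev(dec_lo), rec_hi = rev(dec_hi),
         levels = levels),
    class = "wavelet_spec")
}

# One analysis step of the periodized filter bank: circular correlation
# with the analysis filters followed by dyadic downsampling. Orthogonal
# for any even length (double-shift orthogonality survives periodization).
dwt_step <- function(x, lo, hi) {
  n <- length(x)
  if (n %% 2L != 0L) stop("dwt step requires even length", call. = FALSE)
  L <- length(lo)
  k2 <- 2L * (seq_len(n %/% 2L) - 1L)
  idx <- (outer(k2, 0:(L - 1L), "+") %% n) + 1L
  X <- matrix(x[idx], nrow = n %/% 2L)
  list(a = drop(X %*% lo), d = drop(X %*% hi))
}

# One synthesis step: the adjoint of dwt_step (exact inverse by
# orthogonality). Scatter-add of filter taps at even shifts.
idwt_step <- function(a, d, lo, hi) {
  half <- length(a)
  n <- 2L * half
  L <- length(lo)
  x <- numeric(n)
  k2 <- 2L * (seq_len(half) - 1L)
  for (j in seq_len(L)) {
    p <- ((k2 + (j - 1L)) %% n) + 1L
    x[p] <- x[p] + a * lo[j] + d * hi[j]
  }
  x
}

pad_to_block <- function(x, block) {
  n <- length(x)
  pad <- (block - n %% block) %% block
  if (pad > 0L) x <- c(x, numeric(pad))
  x
}

#' Mallat pyramidal decomposition into approximation and details
#'
#' Decomposes a signal with the dyadic filter-bank cascade and returns
#' every component reconstructed back to full signal length, so that the
#' initial signal equals the level-N approximation plus the N detail
#' components summed pointwise (the multiresolution identity
#' `f0 = fN + dN + ... + d1`).
#'
#' @param x Numeric signal, length >= `2^depth`.
#' @param spec A [wavelet_spec()].
#' @param depth Number of cascade levels (default `spec$levels`).
#' @return Object of class `mallat_decomposition`: list with
#'   `approximation` (numeric, same length as `x`) and `details`
#'   (list `d1`..`dN`, finest first), plus the input length.
#' @examples
#' x <- rnorm(128)
#' md <- dwt_mallat(x)
#' max(abs(x - (md$approximation + Reduce(`+`, md$details)))) # ~1e-15
#' @export
dwt_mallat <- function(x, spec = wavelet_spec(), depth = spec$levels) {
  depth <- as.integer(depth)
  if (depth < 1L) stop("depth must be >= 1", call. = FALSE)
  n0 <- length(x)
  if (n0 < 2L^depth) {
    stop("signal too short for a ", depth, "-level decomposition (need >= ",
         2L^depth, " samples)", call. = FALSE)
  }
  if (any(!is.finite(x))) stop("non-finite values in signal", call. = FALSE)
  xp <- pad_to_block(x, 2L^depth)

  approx <- xp
  detail_coeffs <- vector("list", depth)
  for (j in seq_len(depth)) {
    s <- dwt_step(approx, spec$dec_lo, spec$dec_hi)
    approx <- s$a
    detail_coeffs[[j]] <- s$d
  }

  # lift a coefficient vector at level j back to full length through the
  # synthesis cascade, zeroing the complementary branch at each step
  lift <- function(coef, level, branch) {
    v <- coef
    for (j in level:1L) {
      z <- numeric(length(v))
      v <- if (j == level && branch == "d") {
        idwt_step(z, v, spec$dec_lo, spec$dec_hi)
      } else {
        idwt_step(v, z, spec$dec_lo, spec$dec_hi)
      }
    }
    v[seq_len(n0)]
  }

  details <- lapply(seq_len(depth), function(j) lift(detail_coeffs[[j]], j, "d"))
  names(details) <- paste0("d", seq_len(depth))
  structure(
    list(approximation = lift(approx, depth, "a"),
         details = details,
         depth = depth,
         n_samples = n0),
    class = "mallat_decomposition")
}

#' Full wavelet-packet decomposition
#'
#' Splits both the approximation and the detail branch at every node
#' down to `levels` levels, yielding `2^levels` equal-width subbands.
#' The signal is zero-padded to the next multiple of `2^levels` samples
#' (periodized boundaries); the pad is tracked and removed on
#' reconstruction. Coefficients are stored in natural (Paley) order;
#' use [frequency_order()] to translate node indices to a
#' frequency-monotone indexing.
#'
#' @param x Numeric signal, length >= `2^levels` (16 for the default
#'   four-level depth).
#' @param spec A [wavelet_spec()].
#' @param fs Sampling frequency in Hz (default 128); stored for band
#'   bookkeeping only.
#' @param levels Decomposition depth (default `spec$levels`).
#' @return Object of class `packet_tree`: `coeffs[[l + 1]][[k + 1]]` is
#'   the coefficient vector of node `(l, k)` in natural order
#'   (`l = 0..levels`), plus `levels`, `n_samples`, `n_padded`, `fs`
#'   and the spec.
#' @examples
#' tr <- wpt_decompose(rnorm(64))
#' lengths(tr$coeffs[[5]]) # 16 leaves of 4 coefficients each
#' @export
wpt_decompose <- function(x, spec = wavelet_spec(), fs = 128,
                          levels = spec$levels) {
  levels <- as.integer(levels)
  n0 <- length(x)
  if (n0 < 2L^levels) {
    stop("signal too short for a ", levels, "-level packet decomposition ",
         "(need >= ", 2L^levels, " samples, got ", n0, ")", call. = FALSE)
  }
  if (any(!is.finite(x))) stop("non-finite values in signal", call. = FALSE)
  xp <- pad_to_block(x, 2L^levels)

  coeffs <- vector("list", levels + 1L)
  coeffs[[1L]] <- list(xp)
  for (l in seq_len(levels)) {
    prev <- coeffs[[l]]
    nxt <- vector("list", 2L * length(prev))
    for (i in seq_along(prev)) {
      s <- dwt_step(prev[[i]], spec$dec_lo, spec$dec_hi)
      nxt[[2L * i - 1L]] <- s$a
      nxt[[2L * i]] <- s$d
    }
    coeffs[[l + 1L]] <- nxt
  }
  structure(
    list(coeffs = coeffs, levels = levels,
         n_samples = n0, n_padded = length(xp),
         fs = fs, spec = spec),
    class = "packet_tree")
}

#' Inverse wavelet-packet transform with optional leaf selection
#'
#' Reconstructs the time-domain signal from a packet tree, optionally
#' keeping only a subset of leaves (all others zeroed) — the primitive
#' behind band reconstruction and subband low-pass filtering.
#'
#' @param tree A `packet_tree` from [wpt_decompose()].
#' @param keep Integer vector of leaf indices (0-based, natural order)
#'   to retain; `NULL` keeps all leaves.
#' @return Numeric signal of the original (pre-padding) length.
#' @export
wpt_reconstruct <- function(tree, keep = NULL) {
  stopifnot(inherits(tree, "packet_tree"))
  leaves <- tree$coeffs[[tree$levels + 1L]]
  if (!is.null(keep)) {
    keep <- as.integer(keep)
    if (any(keep < 0L | keep >= length(leaves))) {
      stop("leaf index out of range 0..", length(leaves) - 1L, call. = FALSE)
    }
    drop_idx <- setdiff(seq_along(leaves) - 1L, keep)
    for (i in drop_idx) leaves[[i + 1L]] <- numeric(length(leaves[[i + 1L]]))
  }
  nodes <- leaves
  spec <- tree$spec
  for (l in seq_len(tree$levels)) {
    nxt <- vector("list", length(nodes) %/% 2L)
    for (i in seq_along(nxt)) {
      nxt[[i]] <- idwt_step(nodes[[2L * i - 1L]], nodes[[2L * i]],
                            spec$dec_lo, spec$dec_hi)
    }
    nodes <- nxt
  }
  nodes[[1L]][seq_len(tree$n_samples)]
}

gray_code <- function(n) bitwXor(n, n %/% 2L)

inverse_gray <- function(n) {
  r <- n
  s <- n
  while (any(s > 0L)) {
    s <- s %/% 2L
    r <- bitwXor(r, s)
  }
  r
}

#' Natural (Paley) to frequency node ordering and back
#'
#' In a raw packet tree the high-pass branch aliases, so natural node
#' indices are not frequency-monotone. The Gray-code permutation fixes
#' this: the natural index is the Gray code of the frequency index.
#' Frequency index `k` at level `l` spans `[k, k + 1) * fs/2/2^l` Hz.
#'
#' @param level Tree level (>= 1).
#' @param natural_index,frequency_index 0-based node index (vectorised).
#' @return The corresponding index in the other ordering.
#' @examples
#' frequency_order(2, 0:3) # 0 1 3 2
#' natural_order(4, frequency_order(4, 0:15)) # identity
#' @export
frequency_order <- function(level, natural_index) {
  natural_index <- as.integer(natural_index)
  check_node_index(level, natural_index)
  inverse_gray(natural_index)
}

#' @rdname frequency_order
#' @export
natural_order <- function(level, frequency_index) {
  frequency_index <- as.integer(frequency_index)
  check_node_index(level, frequency_index)
  gray_code(frequency_index)
}

check_node_index <- function(level, idx) {
  level <- as.integer(level)
  if (level < 1L) stop("level must be >= 1", call. = FALSE)
  if (any(idx < 0L | idx >= 2L^level)) {
    stop("node index out of range 0..", 2L^level - 1L,
         " at level ", level, call. = FALSE)
  }
  invisible(TRUE)
}

#' Rhythm-band to subband mapping
#'
#' Maps the four EEG rhythm bands onto frequency-ordered leaves of a
#' four-level packet tree at `fs = 128` Hz (leaf width
#' `fs/2/2^levels = 4` Hz): delta -> leaf 0 (0-4 Hz), theta -> leaf 1
#' (4-8 Hz), alpha -> leaf 2 (8-12 Hz), beta -> leaves 3-7 (12-32 Hz).
#' These are the subband sets actually used for extraction; the
#' narrower nominal physiological edges (e.g. alpha 8-13 Hz) drive the
#' synthetic generator, not the decomposition.
#'
#' @param fs Sampling frequency in Hz.
#' @param levels Packet depth.
#' @param sets Optional custom named list of frequency-ordered leaf
#'   index sets (must be disjoint).
#' @return Object of class `band_map`: named list of leaf index sets
#'   with attributes `delta_f` (leaf width, Hz) and `edges` (nominal
#'   band edges in Hz per band).
#' @examples
#' bm <- band_map()
#' attr(bm, "delta_f") # 4
#' @export
band_map <- function(fs = 128, levels = 4L, sets = NULL) {
  delta_f <- fs / 2 / 2^levels
  if (is.null(sets)) {
    sets <- list(delta = 0L, theta = 1L, alpha = 2L, beta = 3:7)
  }
  all_idx <- unlist(sets)
  if (anyDuplicated(all_idx)) stop("band leaf sets must be disjoint",
                                   call. = FALSE)
  if (any(all_idx < 0 | all_idx >= 2^levels)) {
    stop("leaf index out of range for level ", levels, call. = FALSE)
  }
  edges <- lapply(sets, function(s) c(min(s), max(s) + 1L) * delta_f)
  structure(sets, delta_f = delta_f, edges = edges, levels = levels,
            class = "band_map")
}

#' Reconstruct one rhythm band from a packet tree
#'
#' Zeroes all leaves outside the band's frequency-ordered leaf set and
#' inverts the transform, yielding the time-domain rhythm signal at the
#' original length.
#'
#' @param tree A `packet_tree`.
#' @param band Band name: one of `"delta"`, `"theta"`, `"alpha"`,
#'   `"beta"` (or a name present in `map`).
#' @param map A [band_map()].
#' @return Numeric band signal, same length as the decomposed signal.
#' @export
reconstruct_band <- function(tree, band, map = band_map(tree$fs, tree$levels)) {
  if (!band %in% names(map)) {
    stop("unknown band '", band, "'; available: ",
         paste(names(map), collapse = ", "), call. = FALSE)
  }
  keep_nat <- natural_order(tree$levels, map[[band]])
  wpt_reconstruct(tree, keep = keep_nat)
}
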