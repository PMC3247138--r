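#' Amino acid composition (20 features)
#'
#' Occurrence frequency of each amino acid: `n_A(i) / L`. Entries are
#' nonnegative and sum to 1.
#'
#' @param seq a [protein_sequence].
#' @return named numeric vector of length 20 (alphabetical one-letter order).
#' @export
compute_aac <- function(seq) {
  idx <- seq_index(seq)
  stats::setNames(tabulate(idx, 20L) / seq$length, AMINO_ACIDS)
}

dipeptide_names <- function() {
  paste0(rep(AMINO_ACIDS, each = 20L), rep(AMINO_ACIDS, times = 20L))
}

#' Dipeptide composition (400 features)
#'
#' Occurrence frequency of each of the 400 adjacent residue pairs:
#' `n_D(i) / (L - 1)`. Pair order is first letter major, second letter minor,
#' both alphabetical (AA, AC, ..., AY, CA, ...).
#'
#' @inheritParams compute_aac
#' @return named numeric vector of length 400, summing to 1.
#' @export
compute_dc <- function(seq) {
  idx <- seq_index(seq)
  L <- seq$length
  code <- (idx[-L] - 1L) * 20L + idx[-1L]
  stats::setNames(tabulate(code, 400L) / (L - 1L), dipeptide_names())
}

#' Autocorrelation descriptors (30 lags)
#'
#' Lag-indexed autocorrelation of a standardized physicochemical property
#' signal along the sequence, for lags d = 1..30. Three variants:
#' \describe{
#'   \item{NMB}{normalized Moreau-Broto: `sum(P_i * P_{i+d}) / (L - d)`.}
#'   \item{Moran}{`[sum((P_i - Pbar)(P_{i+d} - Pbar)) / (L - d)] /
#'     [sum((P_i - Pbar)^2) / L]`, with `Pbar` the along-sequence mean.}
#'   \item{Geary}{`[sum((P_i - P_{i+d})^2) / (2(L - d))] /
#'     [sum((P_i - Pbar)^2) / (L - 1)]`.}
#' }
#' When the property signal is constant along the sequence the Moran and Geary
#' denominators vanish; the descriptor is then defined as 0 (no variation, no
#' measurable autocorrelation).
#'
#' @inheritParams compute_aac
#' @param prop a `property_table` with standardized values (properties 1-8 in
#'   the canonical feature vector).
#' @param kind one of `"NMB"`, `"Moran"`, `"Geary"`.
#' @return numeric vector of length 30 (lags 1..30).
#' @export
compute_autocorrelation <- function(seq, prop, kind = c("NMB", "Moran", "Geary")) {
  kind <- match.arg(kind)
  if (is.null(prop$standardized_values)) {
    stop("property ", prop$property_id, " (", prop$name,
         ") has no standardized numeric scale", call. = FALSE)
  }
  L <- seq$length
  if (L <= 30L) stop("sequence too short for lags 1..30", call. = FALSE)
  P <- unname(prop$standardized_values[seq_index(seq)])
  out <- numeric(30L)
  if (kind == "NMB") {
    for (d in 1:30) {
      out[d] <- sum(P[1:(L - d)] * P[(1 + d):L]) / (L - d)
    }
    return(out)
  }
  Pbar <- mean(P)
  ss <- sum((P - Pbar)^2)
  if (ss < 1e-300) return(out)  # constant signal -> all zeros
  if (kind == "Moran") {
    den <- ss / L
    for (d in 1:30) {
      out[d] <- (sum((P[1:(L - d)] - Pbar) * (P[(1 + d):L] - Pbar)) / (L - d)) / den
    }
  } else {
    den <- ss / (L - 1)
    for (d in 1:30) {
      out[d] <- (sum((P[1:(L - d)] - P[(1 + d):L])^2) / (2 * (L - d))) / den
    }
  }
  out
}

# Composition/Transition/Distribution on an integer-recoded sequence.
# g: integer vector in 1..n_groups. Returns c(Comp[n], Tran[choose(n,2)],
# Dist[5n]), all on the percent scale.
ctd_descriptors <- function(g, n_groups = 3L) {
  L <- length(g)
  comp <- 100 * tabulate(g, n_groups) / L
  pairs <- utils::combn(n_groups, 2L)
  a <- g[-L]
  b <- g[-1L]
  tran <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    tran[k] <- 100 * sum((a == i & b == j) | (a == j & b == i)) / (L - 1L)
  }
  dist <- numeric(5L * n_groups)
  for (s in seq_len(n_groups)) {
    pos <- which(g == s)
    n <- length(pos)
    if (n == 0L) next  # absent symbol: five zeros
    take <- c(1L, pmax(1L, floor(c(0.25, 0.5, 0.75, 1) * n)))
    dist[(s - 1L) * 5L + 1:5] <- 100 * pos[take] / L
  }
  c(comp, tran, dist)
}

#' Global (composition/transition/distribution) descriptors (21 features)
#'
#' Recodes the sequence into the 3 symbols of a property grouping scheme and
#' returns, on the percent scale: 3 composition values (occurrence frequency
#' of each group), 3 transition values (for each unordered group pair, the
#' number of adjacent positions switching between the two groups divided by
#' L - 1), and 15 distribution values (for each group, the sequence positions
#' of the first, 25\%, 50\%, 75\% and 100\% occurrence, divided by L; the
#' quantile occurrence index is `max(1, floor(q * n))`). Groups absent from
#' the sequence get five zero distribution values.
#'
#' @inheritParams compute_aac
#' @param scheme a `grouping_scheme` (one of the 7 returned by
#'   [load_constants()]).
#' @return numeric vector of length 21.
#' @export
compute_global_descriptors <- function(seq, scheme) {
  map <- integer(20L)
  for (k in 1:3) map[match(scheme$groups[[k]], AMINO_ACIDS)] <- k
  ctd_descriptors(map[seq_index(seq)], 3L)
}

#' Sequence-order-coupling numbers (30 ranks)
#'
#' The rank-j coupling number is the sum over the sequence of the squared
#' amino-acid distance between residues j apart:
#' `tau(j) = sum_i d(R_i, R_{i+j})^2`, j = 1..30.
#'
#' @inheritParams compute_aac
#' @param dm an `aa_distance` matrix (Grantham or Schneider-Wrede) from
#'   [load_constants()].
#' @return nonnegative numeric vector of length 30.
#' @export
compute_socn <- function(seq, dm) {
  L <- seq$length
  if (L <= 30L) stop("sequence too short for ranks 1..30", call. = FALSE)
  idx <- seq_index(seq)
  tau <- numeric(30L)
  for (j in 1:30) {
    tau[j] <- sum(dm$values[cbind(idx[1:(L - j)], idx[(1 + j):L])]^2)
  }
  tau
}

#' Quasi-sequence-order descriptors (50 features)
#'
#' Mixes amino acid composition with the weighted coupling numbers. With
#' `f` the 20 composition frequencies and `tau` the 30 coupling numbers,
#' the common denominator is `sum(f) + omega * sum(tau)`; entries 1-20 are
#' `f(i)` over it and entries 21-50 are `omega * tau(j)` over it. The 50
#' values sum to 1.
#'
#' @inheritParams compute_socn
#' @param omega weighting factor for the coupling-number term (default 0.1).
#' @return numeric vector of length 50.
#' @export
compute_qso <- function(seq, dm, omega = 0.1) {
  stopifnot(omega > 0)
  f <- compute_aac(seq)
  tau <- compute_socn(seq, dm)
  den <- sum(f) + omega * sum(tau)
  unname(c(f, omega * tau)) / den
}

# 20x20 matrix of squared-difference correlation factors built from the
# standardized hydrophobicity / hydrophilicity / side-chain-mass scales.
pseaac_theta_matrix <- function(props_h) {
  H <- vapply(props_h, function(p) unname(p$standardized_values), numeric(20L))
  TH <- matrix(0, 20L, 20L)
  for (a in 1:20) for (b in 1:20) TH[a, b] <- mean((H[a, ] - H[b, ])^2)
  TH
}

#' Pseudo amino acid composition descriptors (50 features)
#'
#' Composition augmented with 30 tiers of sequence-order correlation factors.
#' The tier-d factor is `theta(d) = mean_i Theta(R_i, R_{i+d})` where
#' `Theta(a, b)` averages the squared differences of the standardized
#' hydrophobicity, hydrophilicity and side-chain-mass values of a and b.
#' Entries are normalized by `sum(f) + omega * sum(theta)` as in [compute_qso]
#' and sum to 1.
#'
#' @inheritParams compute_aac
#' @param props_h list of the three `property_table`s (hydrophobicity,
#'   hydrophilicity, side-chain mass); defaults to properties 9-11 of
#'   [load_constants()].
#' @param omega weighting factor (default 0.1).
#' @return numeric vector of length 50.
#' @export
compute_pseaac <- function(seq, props_h = NULL, omega = 0.1) {
  stopifnot(omega > 0)
  if (is.null(props_h)) props_h <- load_constants()$properties[9:11]
  L <- seq$length
  if (L <= 30L) stop("sequence too short for tiers 1..30", call. = FALSE)
  TH <- pseaac_theta_matrix(props_h)
  idx <- seq_index(seq)
  theta <- numeric(30L)
  for (d in 1:30) {
    theta[d] <- mean(TH[cbind(idx[1:(L - d)], idx[(1 + d):L])])
  }
  f <- compute_aac(seq)
  den <- sum(f) + omega * sum(theta)
  unname(c(f, omega * theta)) / den
}

#' Feature-vector block index
#'
#' Named spans of the 1497-dimensional feature vector:
#' AAC(20), DC(400), AD(720 = 3 kinds x 8 properties x 30 lags),
#' GD(147 = 7 schemes x 21), SD(160 = 2 x 30 coupling numbers +
#' 2 x 50 quasi-sequence-order), PseAAC(50).
#'
#' @return data.frame with columns `block`, `start`, `end`, `length`.
#' @export
feature_blocks <- function() {
  len <- c(AAC = 20L, DC = 400L, AD = 720L, GD = 147L, SD = 160L, PseAAC = 50L)
  end <- cumsum(len)
  data.frame(block = names(len), start = end - len + 1L, end = end,
             length = unname(len), row.names = NULL)
}

feature_names <- function() {
  k <- load_constants()
  ad <- as.vector(vapply(c("NMB", "Moran", "Geary"), function(kind)
    as.vector(vapply(1:8, function(p) paste0("AD_", kind, "_P", p, "_d", 1:30),
                     character(30L))), character(240L)))
  gd <- as.vector(vapply(k$groupings, function(g)
    paste0("GD_P", g$property_id, "_",
           c(paste0("Comp", 1:3), paste0("Tran", c("12", "13", "23")),
             paste0("Dist", rep(1:3, each = 5), "_", rep(1:5, 3)))),
    character(21L)))
  sd_names <- c(paste0("SD_SOCN_grantham_j", 1:30),
                paste0("SD_SOCN_schneider_wrede_j", 1:30),
                paste0("SD_QSO_grantham_", 1:50),
                paste0("SD_QSO_schneider_wrede_", 1:50))
  c(paste0("AAC_", AMINO_ACIDS), paste0("DC_", dipeptide_names()),
    ad, gd, sd_names, paste0("PseAAC_", 1:50))
}

#' Extract the full 1497-dimensional feature vector
#'
#' Concatenates, in fixed documented order, amino acid composition (20),
#' dipeptide composition (400), autocorrelation descriptors (720: kinds
#' NMB/Moran/Geary, each over properties 1-8 and lags 1..30), global
#' descriptors (147: grouping schemes 12-18, 21 each), sequence-order
#' descriptors (160: coupling numbers then quasi-sequence-order, Grantham
#' matrix before Schneider-Wrede), and pseudo amino acid composition (50).
#' Block lengths and the unit sums of all composition-type blocks are
#' asserted on every call.
#'
#' @inheritParams compute_aac
#' @param constants constant set from [load_constants()].
#' @param omega weighting factor passed to [compute_qso] and
#'   [compute_pseaac].
#' @return named numeric vector of length 1497.
#' @examples
#' s <- protein_sequence("ex", strrep("ACDEFGHIKLMNPQRSTVWY", 3))
#' length(extract_features(s))
#' @export
extract_features <- function(seq, constants = load_constants(), omega = 0.1) {
  aac <- compute_aac(seq)
  dc <- compute_dc(seq)
  ad <- unlist(lapply(c("NMB", "Moran", "Geary"), function(kind)
    lapply(constants$properties[1:8], function(p)
      compute_autocorrelation(seq, p, kind))), use.names = FALSE)
  gd <- unlist(lapply(constants$groupings, function(g)
    compute_global_descriptors(seq, g)), use.names = FALSE)
  dms <- constants$distances[c("grantham", "schneider_wrede")]
  socn <- unlist(lapply(dms, compute_socn, seq = seq), use.names = FALSE)
  qso <- unlist(lapply(dms, compute_qso, seq = seq, omega = omega),
                use.names = FALSE)
  pse <- compute_pseaac(seq, constants$properties[9:11], omega)
  v <- c(unname(aac), unname(dc), ad, gd, socn, qso, pse)

  stopifnot(length(v) == 1497L, length(ad) == 720L, length(gd) == 147L,
            length(socn) + length(qso) == 160L,
            abs(sum(aac) - 1) < 1e-9, abs(sum(dc) - 1) < 1e-9,
            abs(sum(qso[1:50]) - 1) < 1e-9, abs(sum(qso[51:100]) - 1) < 1e-9,
            abs(sum(pse) - 1) < 1e-9)
  stats::setNames(v, feature_names())
}

#' Extract features for a list of sequences
#'
#' @param seqs list of [protein_sequence] objects.
#' @inheritParams extract_features
#' @return numeric matrix, one row per sequence (rownames = sequence ids),
#'   1497 named columns.
#' @export
extract_features_matrix <- function(seqs, constants = load_constants(),
                                    omega = 0.1) {
  stopifnot(length(seqs) >= 1L)
  rows <- lapply(seqs, extract_features, constants = constants, omega = omega)
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(seqs, function(s) s$id, character(1L))
  m
}
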