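# ProA: sequence-derived physicochemical protein descriptors, in seven
# groups: amino-acid composition, autocorrelation (Moreau-Broto / Moran /
# Geary over 8 property scales, lag <= 30), CTD
# (composition/transition/distribution over 7 property partitions),
# conjoint triad (343), quasi-sequence-order (SOCN + QSO, maxlag 30),
# type-I pseudo-amino-acid composition (lambda 30), and principal-property
# window statistics. Groups whose raw dimensionality exceeds 50 are
# PCA-compressed at the panel level (see compute_proa_panel).

.tf_aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Published per-residue property scales (rows = residues in .tf_aa order):
# Kyte-Doolittle hydropathy; Hopp-Woods hydrophilicity; residue mass;
# side-chain volume (Zamyatnin); Grantham polarity; Grantham composition;
# isoelectric point; Chou-Fasman alpha-helix propensity.
tf_aa_properties <- function() {
  p <- rbind(
    hydropathy    = c(A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
                      G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
                      M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
                      S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3),
    hydrophilicity = c(A = -0.5, C = -1.0, D =  3.0, E =  3.0, F = -2.5,
                      G =  0.0, H = -0.5, I = -1.8, K =  3.0, L = -1.8,
                      M = -1.3, N =  0.2, P =  0.0, Q =  0.2, R =  3.0,
                      S =  0.3, T = -0.4, V = -1.5, W = -3.4, Y = -2.3),
    mass          = c(A = 71.08, C = 103.14, D = 115.09, E = 129.12,
                      F = 147.18, G = 57.05, H = 137.14, I = 113.16,
                      K = 128.17, L = 113.16, M = 131.19, N = 114.10,
                      P = 97.12, Q = 128.13, R = 156.19, S = 87.08,
                      T = 101.10, V = 99.13, W = 186.21, Y = 163.18),
    volume        = c(A = 88.6, C = 108.5, D = 111.1, E = 138.4,
                      F = 189.9, G = 60.1, H = 153.2, I = 166.7,
                      K = 168.6, L = 166.7, M = 162.9, N = 114.1,
                      P = 112.7, Q = 143.8, R = 173.4, S = 89.0,
                      T = 116.1, V = 140.0, W = 227.8, Y = 193.6),
    polarity      = c(A = 8.1, C = 5.5, D = 13.0, E = 12.3, F = 5.2,
                      G = 9.0, H = 10.4, I = 5.2, K = 11.3, L = 4.9,
                      M = 5.7, N = 11.6, P = 8.0, Q = 10.5, R = 10.5,
                      S = 9.2, T = 8.6, V = 5.9, W = 5.4, Y = 6.2),
    composition   = c(A = 0.00, C = 2.75, D = 1.38, E = 0.92, F = 0.00,
                      G = 0.74, H = 0.58, I = 0.00, K = 0.33, L = 0.00,
                      M = 0.00, N = 1.33, P = 0.39, Q = 0.89, R = 0.65,
                      S = 1.42, T = 0.71, V = 0.00, W = 0.13, Y = 0.20),
    pI            = c(A = 6.00, C = 5.07, D = 2.77, E = 3.22, F = 5.48,
                      G = 5.97, H = 7.59, I = 6.02, K = 9.74, L = 5.98,
                      M = 5.74, N = 5.41, P = 6.30, Q = 5.65, R = 10.76,
                      S = 5.68, T = 5.60, V = 5.96, W = 5.89, Y = 5.66),
    helix         = c(A = 1.42, C = 0.70, D = 1.01, E = 1.51, F = 1.13,
                      G = 0.57, H = 1.00, I = 1.08, K = 1.16, L = 1.21,
                      M = 1.45, N = 0.67, P = 0.57, Q = 1.11, R = 0.98,
                      S = 0.77, T = 0.83, V = 1.06, W = 1.08, Y = 0.69))
  p[, .tf_aa]
}

# Five orthogonal "principal property" scales derived by PCA of the
# standardized property table (the construction used for proteochemometric
# z-scales). Deterministic: sign fixed so the largest loading is positive.
tf_principal_properties <- function(k = 5) {
  p <- tf_aa_properties()
  z <- t(scale(t(p)))           # standardize each scale across residues
  pc <- stats::prcomp(t(z), center = TRUE, scale. = FALSE)
  sc <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) if (sc[which.max(abs(sc[, j])), j] < 0) sc[, j] <- -sc[, j]
  t(sc)                          # k x 20, columns in .tf_aa order
}

# CTD three-class partitions (Dubchak): each row assigns residues to
# classes 1..3 for one property.
.tf_ctd_groups <- list(
  hydrophobicity = c(polar = "RKEDQN", neutral = "GASTPHY", hydrophobic = "CLVIMFW"),
  vdw_volume     = c(small = "GASTPDC", medium = "NVEQIL", large = "MHKFRYW"),
  polarity       = c(low = "LIFWCMVY", medium = "PATGS", high = "HQRKNED"),
  polarizability = c(low = "GASDT", medium = "CPNVEQIL", high = "KMHFRYW"),
  charge         = c(positive = "KR", neutral = "ANCQGHILMFPSTWYV", negative = "DE"),
  secondary      = c(helix = "EALMQKRH", strand = "VIYCWFT", coil = "GNPSD"),
  accessibility  = c(buried = "ALFCGIVW", exposed = "RKQEND", intermediate = "MSPTHY"))

# Conjoint-triad residue classes (7).
.tf_ct_classes <- c("AGV", "ILFP", "YMTS", "HNQW", "RK", "DE", "C")

tf_seq_ints <- function(sequence) match(strsplit(sequence, "")[[1]], .tf_aa)

#' Raw ProA descriptor groups for one protein
#'
#' @param sequence amino-acid string (canonical 20-letter alphabet).
#' @param maxlag autocorrelation / sequence-order lag bound (default 30);
#'   reduced to `nchar(sequence) - 1` with a warning on short sequences.
#' @return named list of numeric vectors: `aac` (20), `auto_<scale>`
#'   (90 each, 8 scales), `ctd_c` (21), `ctd_t` (21), `ctd_d` (105),
#'   `ctriad` (343), `socn` (maxlag), `qso` (20 + maxlag),
#'   `paac` (20 + lambda), `zwin_mean` (35), `zwin_sd` (35).
#' @export
compute_proa_raw <- function(sequence, maxlag = 30L) {
  si <- tf_seq_ints(sequence)
  if (anyNA(si)) stop("non-canonical residue in sequence", call. = FALSE)
  L <- length(si)
  if (L <= maxlag) {
    warning("sequence length ", L, " <= maxlag; lag reduced to ", L - 1L,
            call. = FALSE)
    maxlag <- L - 1L
  }
  out <- list()
  # 1. amino-acid composition
  comp <- tabulate(si, nbins = 20) / L
  names(comp) <- .tf_aa
  out$aac <- comp

  # 2. autocorrelation over 8 standardized scales
  props <- tf_aa_properties()
  zprops <- t(scale(t(props)))
  for (s in rownames(zprops)) {
    x <- zprops[s, si]
    xbar <- mean(x)
    mb <- mo <- ge <- numeric(30)
    denom_mo <- sum((x - xbar)^2) / L
    for (d in seq_len(min(maxlag, 30L))) {
      a <- x[1:(L - d)]; b <- x[(1 + d):L]
      mb[d] <- sum(a * b) / (L - d)
      mo[d] <- if (denom_mo > 0) (sum((a - xbar) * (b - xbar)) / (L - d)) / denom_mo else 0
      ge[d] <- if (denom_mo > 0)
        (sum((a - b)^2) / (2 * (L - d))) / (sum((x - xbar)^2) / (L - 1)) else 0
    }
    out[[paste0("auto_", s)]] <- c(mb, mo, ge)
  }

  # 3. CTD
  cc <- tt <- numeric(0); dd <- numeric(0)
  for (gname in names(.tf_ctd_groups)) {
    grp <- .tf_ctd_groups[[gname]]
    cls <- integer(20)
    for (k in 1:3) cls[match(strsplit(grp[k], "")[[1]], .tf_aa)] <- k
    cs <- cls[si]
    cc <- c(cc, tabulate(cs, 3) / L)
    pairs <- cbind(cs[-L], cs[-1])
    t12 <- sum((pairs[, 1] == 1 & pairs[, 2] == 2) | (pairs[, 1] == 2 & pairs[, 2] == 1))
    t13 <- sum((pairs[, 1] == 1 & pairs[, 2] == 3) | (pairs[, 1] == 3 & pairs[, 2] == 1))
    t23 <- sum((pairs[, 1] == 2 & pairs[, 2] == 3) | (pairs[, 1] == 3 & pairs[, 2] == 2))
    tt <- c(tt, c(t12, t13, t23) / max(1, L - 1))
    for (k in 1:3) {
      pos <- which(cs == k)
      if (!length(pos)) { dd <- c(dd, rep(0, 5)); next }
      qs <- ceiling(c(1, 0.25, 0.5, 0.75, 1) * length(pos))
      qs[1] <- 1
      dd <- c(dd, pos[qs] / L * 100)
    }
  }
  out$ctd_c <- cc; out$ctd_t <- tt; out$ctd_d <- dd

  # 4. conjoint triad
  ct_cls <- integer(20)
  for (k in seq_along(.tf_ct_classes))
    ct_cls[match(strsplit(.tf_ct_classes[k], "")[[1]], .tf_aa)] <- k
  cs <- ct_cls[si]
  tri <- numeric(343)
  if (L >= 3) {
    idx <- (cs[1:(L - 2)] - 1) * 49 + (cs[2:(L - 1)] - 1) * 7 + cs[3:L]
    tb <- tabulate(idx, nbins = 343)
    tri <- if (max(tb) > 0) tb / max(tb) else tb   # normalized frequencies
  }
  out$ctriad <- tri

  # 5. quasi-sequence-order (distance = Euclidean over standardized scales)
  dmat <- as.matrix(stats::dist(t(zprops)))
  tau <- vapply(seq_len(maxlag), function(d)
    sum(dmat[cbind(si[1:(L - d)], si[(1 + d):L])]^2), numeric(1))
  w <- 0.1
  denom <- sum(comp) + w * sum(tau)
  out$socn <- tau
  out$qso <- c(comp / denom, w * tau / denom)

  # 6. type-I pseudo-amino-acid composition, lambda = maxlag
  corr <- function(i, j) mean((zprops[, i] - zprops[, j])^2)
  cmat <- outer(1:20, 1:20, Vectorize(corr))
  theta <- vapply(seq_len(maxlag), function(d)
    mean(cmat[cbind(si[1:(L - d)], si[(1 + d):L])]), numeric(1))
  wp <- 0.05
  den <- 1 + wp * sum(theta)
  out$paac <- c(comp / den, wp * theta / den)

  # 7. principal-property window statistics: 5 scales x 7 windows,
  # per-window mean and sd
  pp <- tf_principal_properties(5)
  xs <- pp[, si, drop = FALSE]
  brks <- floor(seq(0, L, length.out = 8))
  zm <- zs <- matrix(0, 5, 7)
  for (wnd in 1:7) {
    cols <- (brks[wnd] + 1):brks[wnd + 1]
    zm[, wnd] <- rowMeans(xs[, cols, drop = FALSE])
    zs[, wnd] <- apply(xs[, cols, drop = FALSE], 1, stats::sd)
  }
  zs[is.na(zs)] <- 0
  out$zwin_mean <- as.numeric(zm)
  out$zwin_sd <- as.numeric(zs)
  out
}

# Raw group matrix over a panel: list of matrices (proteins x raw dims).
tf_proa_raw_panel <- function(panel, maxlag = 30L) {
  raws <- lapply(panel$sequences, compute_proa_raw, maxlag = maxlag)
  groups <- names(raws[[1]])
  out <- lapply(groups, function(g)
    do.call(rbind, lapply(raws, function(r) r[[g]])))
  names(out) <- groups
  for (g in groups) rownames(out[[g]]) <- panel$ids
  out
}
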