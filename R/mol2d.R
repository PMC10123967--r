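# Mol2D: 188 two-dimensional molecular descriptors in seven families:
# 30 constitutional, 25 topological, 44 connectivity (chi) indices,
# 7 kappa shape indices, 21 Basak information indices, 25 Gasteiger-charge
# descriptors and 36 MOE-type (property-binned approximate van der Waals
# surface area) descriptors. All are computed from the heavy-atom graph of
# a `tf_mol`; no 3D conformation is used. The fixed descriptor order is
# recorded in the shipped manifest (inst/extdata/mol2d_manifest.json).

.tf_atomic_mass <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                     F = 18.998, P = 30.974, S = 32.06, Cl = 35.45,
                     Br = 79.904, I = 126.904, B = 10.811, Si = 28.086)
.tf_atomic_number <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14,
                       P = 15, S = 16, Cl = 17, Br = 35, I = 53)
.tf_valence_electrons <- c(H = 1, B = 3, C = 4, N = 5, O = 6, F = 7,
                           Si = 4, P = 5, S = 6, Cl = 7, Br = 7, I = 7)
.tf_vdw_radius <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
                    P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98,
                    B = 1.92, Si = 2.10)
.tf_cov_radius <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
                    P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20, I = 1.39,
                    B = 0.84, Si = 1.11)
.tf_polarizability <- c(H = 0.667, C = 1.76, N = 1.10, O = 0.802,
                        F = 0.557, P = 3.63, S = 2.90, Cl = 2.18,
                        Br = 3.05, I = 5.35, B = 3.03, Si = 5.38)
# Kier alpha contributions relative to sp3 carbon, keyed by SYBYL type.
.tf_kier_alpha <- c("C.3" = 0, "C.cat" = 0, "C.2" = -0.13, "C.ar" = -0.13,
                    "C.1" = -0.22, "N.3" = -0.04, "N.am" = -0.04,
                    "N.pl3" = -0.04, "N.4" = -0.04, "N.2" = -0.20,
                    "N.ar" = -0.20, "N.1" = -0.29, "O.3" = -0.04,
                    "O.2" = -0.20, "O.co2" = -0.20, "F" = -0.07,
                    "Cl" = 0.29, "Br" = 0.48, "I" = 0.73, "S.3" = 0.35,
                    "S.2" = 0.35, "S.o" = 0.35, "S.o2" = 0.35, "P.3" = 0.43)
# Coarse atomic lipophilicity contributions for the hydrophobicity-binned
# surface-area descriptors (an intentionally simple Crippen-style scheme).
.tf_logp_contrib <- function(sybyl) {
  elem <- sub("\\..*$", "", sybyl)
  v <- numeric(length(sybyl))
  v[elem == "C"] <- 0.14
  v[sybyl == "C.ar"] <- 0.29
  v[elem == "N"] <- -0.60
  v[sybyl == "N.ar"] <- -0.49
  v[sybyl == "O.3"] <- -0.40
  v[elem == "O" & sybyl != "O.3"] <- -0.12
  v[elem == "S"] <- 0.25
  v[elem == "P"] <- -0.45
  v[elem == "F"] <- 0.22
  v[elem == "Cl"] <- 0.65
  v[elem == "Br"] <- 0.86
  v[elem == "I"] <- 1.10
  v
}

tf_mol_graph <- function(mol) {
  g <- igraph::make_empty_graph(n = mol$n_heavy, directed = FALSE)
  if (nrow(mol$bonds))
    g <- igraph::add_edges(g, c(rbind(mol$bonds$a1, mol$bonds$a2)))
  igraph::set_vertex_attr(g, "name", value = as.character(seq_len(mol$n_heavy)))
}

# All simple paths of length 1..maxlen (edge counts); returns a list with,
# per length, the matrix-free sums needed by the chi indices.
tf_enumerate_paths <- function(adj, maxlen) {
  n <- length(adj)
  paths <- vector("list", maxlen)
  for (h in seq_len(maxlen)) paths[[h]] <- list()
  for (start in seq_len(n)) {
    stack <- list(c(start))
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      last <- p[length(p)]
      for (u in adj[[last]]) {
        if (u %in% p) next
        p2 <- c(p, u)
        h <- length(p2) - 1L
        if (p2[1] < p2[length(p2)]) paths[[h]][[length(paths[[h]]) + 1L]] <- p2
        if (h < maxlen) stack[[length(stack) + 1L]] <- p2
      }
    }
  }
  paths
}

# Connected edge-subgraphs with exactly k edges (k small); returns a list of
# integer edge-index vectors, each subgraph once.
tf_edge_subgraphs <- function(bonds, k) {
  m <- nrow(bonds)
  if (m < k) return(list())
  # adjacency between edges (sharing a vertex)
  eadj <- vector("list", m)
  for (i in seq_len(m)) {
    sh <- which((bonds$a1 == bonds$a1[i]) | (bonds$a2 == bonds$a1[i]) |
                (bonds$a1 == bonds$a2[i]) | (bonds$a2 == bonds$a2[i]))
    eadj[[i]] <- setdiff(sh, i)
  }
  seen <- new.env(hash = TRUE, parent = emptyenv())
  out <- list()
  grow <- function(set, frontier) {
    if (length(set) == k) {
      key <- paste(sort(set), collapse = ",")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        out[[length(out) + 1L]] <<- set
      }
      return()
    }
    for (e in frontier) {
      if (e %in% set) next
      grow(c(set, e), union(frontier, eadj[[e]]))
    }
  }
  for (e0 in seq_len(m)) grow(e0, eadj[[e0]])
  out
}

tf_subgraph_class <- function(bonds, eset) {
  vs <- unique(c(bonds$a1[eset], bonds$a2[eset]))
  if (length(vs) != length(eset) + 1L) return("cyclic")
  degs <- tabulate(match(c(bonds$a1[eset], bonds$a2[eset]), vs),
                   nbins = length(vs))
  if (max(degs) == length(eset)) return("cluster")
  if (max(degs) <= 2) return("path")
  "pathcluster"
}

tf_chi_sum <- function(bonds, esets, delta) {
  s <- 0
  for (eset in esets) {
    vs <- unique(c(bonds$a1[eset], bonds$a2[eset]))
    d <- delta[vs]
    if (any(d <= 0)) next
    s <- s + prod(1 / sqrt(d))
  }
  s
}

# Kier-Hall valence delta.
tf_valence_delta <- function(mol) {
  elem <- mol$atoms$elem
  zv <- unname(.tf_valence_electrons[elem])
  z <- unname(.tf_atomic_number[elem])
  dv <- zv - mol$atoms$nH
  hi <- !is.na(z) & z > 10
  dv[hi] <- (zv[hi] - mol$atoms$nH[hi]) / (z[hi] - zv[hi] - 1)
  dv
}

tf_shannon <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

# Approximate accessible van der Waals surface area per heavy atom
# (Labute-style sphere-cap subtraction over bonds, implicit H included).
tf_atom_vsa <- function(mol) {
  elem <- mol$atoms$elem
  R <- unname(.tf_vdw_radius[elem]); R[is.na(R)] <- 1.7
  rc <- unname(.tf_cov_radius[elem]); rc[is.na(rc)] <- 0.77
  area <- 4 * pi * R^2
  scale_order <- function(o) ifelse(o >= 3, 0.78, ifelse(o >= 2, 0.87,
                                    ifelse(o > 1, 0.92, 1)))
  cap <- function(Ri, Rj, d) {
    x <- (d^2 - Rj^2 + Ri^2) / (2 * d)
    h <- pmax(0, pmin(Ri - x, 2 * Ri))
    2 * pi * Ri * h
  }
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$a1[k]; j <- mol$bonds$a2[k]
    d <- (rc[i] + rc[j]) * scale_order(mol$bonds$order[k])
    area[i] <- area[i] - cap(R[i], R[j], d)
    area[j] <- area[j] - cap(R[j], R[i], d)
  }
  dH <- rc + .tf_cov_radius[["H"]]
  area <- area - mol$atoms$nH * cap(R, .tf_vdw_radius[["H"]], dH)
  pmax(area, 0)
}

.tf_peoe_breaks <- c(-Inf, -0.25, -0.20, -0.15, -0.10, -0.05, 0,
                     0.05, 0.10, 0.15, 0.20, 0.25, Inf)
.tf_slogp_breaks <- c(-Inf, -0.55, -0.45, -0.35, -0.20, -0.05, 0.05,
                      0.18, 0.26, 0.40, 0.70, 0.95, Inf)
.tf_smr_breaks <- c(-Inf, 0.70, 0.90, 1.20, 1.50, 1.80, 2.00,
                    2.50, 3.00, 3.30, 4.00, 5.00, Inf)

tf_binned_vsa <- function(vsa, prop, breaks) {
  bin <- cut(prop, breaks = breaks, labels = FALSE, right = FALSE)
  vapply(seq_len(length(breaks) - 1L),
         function(b) sum(vsa[bin == b]), numeric(1))
}

#' Descriptor names of the Mol2D block, with family labels
#' @return data.frame with columns `index`, `name`, `family` (188 rows).
#' @export
mol2d_manifest <- function() {
  nm <- c(
    # constitutional (30)
    "natom", "nC", "nN", "nO", "nS", "nP", "nF", "nCl", "nBr", "nI",
    "nhal", "nhet", "nH", "nbond", "nsingle", "ndouble", "ntriple",
    "naromatic", "nring", "naromatom", "nrot", "MW", "AMW", "fracarom",
    "nHBD", "nHBA", "nCsp3", "nCsp2", "nbranch", "nterminal",
    # topological (25)
    "wiener", "meanwiener", "harary", "hyperwiener", "zagreb1", "zagreb2",
    "platt", "diameter", "radius", "petitjean", "meanecc", "eccconn",
    "balabanj", "polarity", "schultz", "density", "adjsum", "maxdrow",
    "meandrow", "vardeg", "meandeg", "maxdeg", "distentropy", "logwiener",
    "meansqdist",
    # connectivity (44)
    sprintf("chi%dp", 0:10), sprintf("chiv%dp", 0:10),
    "chi3c", "chi4c", "chiv3c", "chiv4c",
    "chi4pc", "chi5pc", "chi6pc", "chiv4pc", "chiv5pc", "chiv6pc",
    sprintf("mchi%dp", 0:5), sprintf("mchiv%dp", 0:5),
    # kappa (7)
    "kappa1", "kappa2", "kappa3", "kappa1a", "kappa2a", "kappa3a", "phi",
    # Basak (21)
    sprintf("IC%d", 0:6), sprintf("SIC%d", 0:6), sprintf("CIC%d", 0:6),
    # charge (25)
    "qmax", "qmin", "qpos", "qneg", "qabs", "qmean", "qmeanabs", "qvar",
    "relqmax", "relqmin", "qmaxC", "qminC", "qmeanC", "qmaxN", "qminN",
    "qmaxO", "qminO", "ldimean", "ldisum", "qsquared", "qspread",
    "qhetabs", "fracqpos", "fracqneg", "qrms",
    # MOE-type (36)
    sprintf("peoe_vsa%02d", 1:12), sprintf("slogp_vsa%02d", 1:12),
    sprintf("smr_vsa%02d", 1:12))
  fam <- c(rep("constitutional", 30), rep("topological", 25),
           rep("connectivity", 44), rep("kappa", 7), rep("basak", 21),
           rep("charge", 25), rep("moe", 36))
  data.frame(index = seq_along(nm), name = nm, family = fam,
             stringsAsFactors = FALSE)
}

#' Compute the 188 Mol2D descriptors for one structure
#'
#' @param mol a `tf_mol` (see [parse_compounds()]).
#' @return named numeric vector of length 188; any non-finite value is
#'   replaced by 0 with a warning.
#' @export
compute_mol2d <- function(mol) {
  stopifnot(inherits(mol, "tf_mol"))
  at <- mol$atoms; bd <- mol$bonds
  n <- mol$n_heavy; m <- nrow(bd)
  elem <- at$elem
  deg <- at$degree

  cnt <- function(e) sum(elem == e)
  nH <- sum(at$nH)
  mass <- sum(.tf_atomic_mass[elem], na.rm = TRUE) + nH * .tf_atomic_mass[["H"]]
  g <- tf_mol_graph(mol)
  comp <- igraph::components(g)$no
  nring <- m - n + comp
  # ring-membership of bonds: non-bridge edges lie on a cycle
  in_ring <- rep(FALSE, m)
  if (nring > 0 && m > 0) {
    for (k in seq_len(m)) {
      g2 <- igraph::delete_edges(g, k)
      in_ring[k] <- igraph::distances(g2, v = bd$a1[k], to = bd$a2[k]) < Inf
    }
  }
  nrot <- sum(bd$type == "1" & !in_ring & deg[bd$a1] > 1 & deg[bd$a2] > 1)
  hbd <- sum(elem %in% c("N", "O") & at$nH > 0)
  hba <- sum(elem %in% c("N", "O"))
  const <- c(n, cnt("C"), cnt("N"), cnt("O"), cnt("S"), cnt("P"),
             cnt("F"), cnt("Cl"), cnt("Br"), cnt("I"),
             sum(elem %in% c("F", "Cl", "Br", "I")), sum(elem != "C"),
             nH, m, sum(bd$type %in% c("1", "am")), sum(bd$type == "2"),
             sum(bd$type == "3"), sum(bd$type == "ar"), nring,
             sum(at$aromatic), nrot, mass, mass / max(1, n + nH),
             sum(at$aromatic) / max(1, n), hbd, hba,
             sum(at$sybyl == "C.3"), sum(at$sybyl %in% c("C.2", "C.ar")),
             sum(deg >= 3), sum(deg == 1))

  # topological
  D <- igraph::distances(g)
  Df <- D; Df[!is.finite(Df)] <- 0
  pairs <- Df[upper.tri(Df)]
  W <- sum(pairs)
  npair <- max(1, n * (n - 1) / 2)
  rowsum_d <- rowSums(Df)
  ecc <- if (n > 1) apply(Df, 1, max) else 0
  diam <- max(ecc); rad <- if (n > 1) min(ecc) else 0
  z1 <- sum(deg^2); z2 <- sum(deg[bd$a1] * deg[bd$a2])
  balaban <- if (m > 0 && all(rowsum_d[c(bd$a1, bd$a2)] > 0))
    m / (nring + 1) * sum(1 / sqrt(rowsum_d[bd$a1] * rowsum_d[bd$a2])) else 0
  A <- matrix(0, n, n)
  if (m > 0) { A[cbind(bd$a1, bd$a2)] <- 1; A[cbind(bd$a2, bd$a1)] <- 1 }
  schultz <- sum((A + Df) %*% deg)
  dist_tab <- table(pairs[pairs > 0])
  topo <- c(W, W / npair, sum(1 / pairs[pairs > 0]),
            0.5 * sum(pairs + pairs^2), z1, z2,
            if (m > 0) sum(deg[bd$a1] + deg[bd$a2] - 2) else 0,
            diam, rad, if (rad > 0) (diam - rad) / rad else 0,
            mean(ecc), sum(ecc * deg), balaban, sum(pairs == 3), schultz,
            if (n > 1) m / npair else 0, 2 * m, max(rowsum_d), mean(rowsum_d),
            stats::var(c(deg, if (n == 1) NA)) , mean(deg), max(deg, 0),
            if (length(dist_tab)) tf_shannon(as.numeric(dist_tab)) else 0,
            log(1 + W), sum(pairs^2) / npair)
  topo[is.na(topo)] <- 0

  # connectivity
  adj <- lapply(seq_len(n), function(v) c(bd$a2[bd$a1 == v], bd$a1[bd$a2 == v]))
  delta <- deg
  dv <- tf_valence_delta(mol)
  chi_atom <- function(d) sum(1 / sqrt(d[d > 0]))
  paths <- tf_enumerate_paths(adj, 10L)
  chi_path <- function(d) vapply(1:10, function(h) {
    s <- 0
    for (p in paths[[h]]) { dd <- d[p]; if (all(dd > 0)) s <- s + prod(1 / sqrt(dd)) }
    s
  }, numeric(1))
  chp <- c(chi_atom(delta), chi_path(delta))
  chv <- c(chi_atom(dv), chi_path(dv))
  sub3 <- tf_edge_subgraphs(bd, 3L); sub4 <- tf_edge_subgraphs(bd, 4L)
  sub5 <- tf_edge_subgraphs(bd, 5L); sub6 <- tf_edge_subgraphs(bd, 6L)
  cls3 <- vapply(sub3, function(e) tf_subgraph_class(bd, e), character(1))
  cls4 <- vapply(sub4, function(e) tf_subgraph_class(bd, e), character(1))
  cls5 <- vapply(sub5, function(e) tf_subgraph_class(bd, e), character(1))
  cls6 <- vapply(sub6, function(e) tf_subgraph_class(bd, e), character(1))
  chi_set <- function(esets, d) tf_chi_sum(bd, esets, d)
  conn_extra <- c(chi_set(sub3[cls3 == "cluster"], delta),
                  chi_set(sub4[cls4 == "cluster"], delta),
                  chi_set(sub3[cls3 == "cluster"], dv),
                  chi_set(sub4[cls4 == "cluster"], dv),
                  chi_set(sub4[cls4 == "pathcluster"], delta),
                  chi_set(sub5[cls5 == "pathcluster"], delta),
                  chi_set(sub6[cls6 == "pathcluster"], delta),
                  chi_set(sub4[cls4 == "pathcluster"], dv),
                  chi_set(sub5[cls5 == "pathcluster"], dv),
                  chi_set(sub6[cls6 == "pathcluster"], dv))
  pcount <- c(n, vapply(paths[1:5], length, numeric(1)))
  mchp <- ifelse(pcount > 0, chp[1:6] / pcount, 0)
  mchv <- ifelse(pcount > 0, chv[1:6] / pcount, 0)
  conn <- c(chp, chv, conn_extra, mchp, mchv)

  # kappa
  p1 <- m; p2 <- length(paths[[2]]); p3 <- length(paths[[3]])
  alpha <- sum(.tf_kier_alpha[at$sybyl], na.rm = TRUE)
  kap <- function(Aa, P, kind) {
    if (P <= 0) return(0)
    switch(kind,
           k1 = Aa * (Aa - 1)^2 / P^2,
           k2 = (Aa - 1) * (Aa - 2)^2 / P^2,
           k3 = if (round(Aa) %% 2 == 1) (Aa - 1) * (Aa - 3)^2 / P^2
                else (Aa - 3) * (Aa - 2)^2 / P^2)
  }
  k1 <- kap(n, p1, "k1"); k2 <- kap(n, p2, "k2"); k3 <- kap(n, p3, "k3")
  k1a <- kap(n + alpha, p1 + alpha, "k1")
  k2a <- kap(n + alpha, p2 + alpha, "k2")
  k3a <- kap(n + alpha, p3 + alpha, "k3")
  kappa <- c(k1, k2, k3, k1a, k2a, k3a, k1a * k2a / max(1, n))

  # Basak information indices: iterative neighbourhood refinement of atom
  # classes starting from (element, implicit-H count)
  lab <- paste(elem, at$nH, sep = "_")
  ics <- numeric(7); sics <- numeric(7); cics <- numeric(7)
  logn <- if (n > 1) log2(n) else 1
  for (r in 0:6) {
    ic <- tf_shannon(as.numeric(table(lab)))
    ics[r + 1] <- ic
    sics[r + 1] <- if (n > 1) ic / logn else 0
    cics[r + 1] <- max(0, logn - ic) * (n > 1)
    lab <- vapply(seq_len(n), function(v) {
      nb <- sort(paste(bd$order[bd$a1 == v | bd$a2 == v],
                       lab[setdiff(c(bd$a2[bd$a1 == v], bd$a1[bd$a2 == v]), v)],
                       sep = ":"))
      paste(lab[v], paste(nb, collapse = "|"), sep = ">")
    }, character(1))
  }
  # re-map long labels to ids to keep them bounded
  basak <- c(ics, sics, cics)

  # charge
  q <- at$charge
  qpos <- sum(q[q > 0]); qneg <- sum(q[q < 0])
  sel <- function(e, f, default = 0) if (any(elem == e)) f(q[elem == e]) else default
  dq <- abs(q[bd$a1] - q[bd$a2])
  charge <- c(max(q), min(q), qpos, qneg, sum(abs(q)), mean(q), mean(abs(q)),
              stats::var(c(q, if (n == 1) NA)),
              if (qpos > 0) max(q) / qpos else 0,
              if (qneg < 0) min(q) / qneg else 0,
              sel("C", max), sel("C", min), sel("C", mean),
              sel("N", max), sel("N", min), sel("O", max), sel("O", min),
              if (m > 0) mean(dq) else 0, sum(dq), sum(q^2),
              max(q) - min(q), sum(abs(q[elem != "C"])),
              mean(q > 0), mean(q < 0), sqrt(mean(q^2)))
  charge[is.na(charge)] <- 0

  # MOE-type binned surface areas
  vsa <- tf_atom_vsa(mol)
  pol <- unname(.tf_polarizability[elem]); pol[is.na(pol)] <- 1.5
  moe <- c(tf_binned_vsa(vsa, q, .tf_peoe_breaks),
           tf_binned_vsa(vsa, .tf_logp_contrib(at$sybyl), .tf_slogp_breaks),
           tf_binned_vsa(vsa, pol, .tf_smr_breaks))

  out <- c(const, topo, conn, kappa, basak, charge, moe)
  names(out) <- mol2d_manifest()$name
  bad <- !is.finite(out)
  if (any(bad)) {
    warning("non-finite Mol2D value(s) replaced by 0: ",
            paste(names(out)[bad], collapse = ", "), call. = FALSE)
    out[bad] <- 0
  }
  out
}

#' @rdname compute_mol2d
#' @param compounds a `tf_compounds` object.
#' @export
compute_mol2d_matrix <- function(compounds) {
  stopifnot(inherits(compounds, "tf_compounds"))
  mat <- t(vapply(compounds$mols, compute_mol2d, numeric(188)))
  rownames(mat) <- compounds$ids
  mat
}
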