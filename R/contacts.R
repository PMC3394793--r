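## Geometric trajectory analyses: hydrogen bonds, water bridges, hydrophobic
## pairs, radius of gyration and torsions.  A "frame" is a data frame with
## columns id, x, y, z, element, role, molecule, h_parent (the layout produced
## by build_planted_scene() and the extended-XYZ reader).

## internal: pairwise distance between two position matrices
pair_dist <- function(a, b) {
  sqrt(outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b))
}

frame_xyz <- function(frame, idx) {
  as.matrix(frame[match(idx, frame$id), c("x", "y", "z"), drop = FALSE])
}

#' Detect direct hydrogen bonds in a frame
#'
#' A donor-H/acceptor triple is counted when the donor--acceptor distance is
#' strictly below `max_da_distance` and the D-H...A deviation from linearity
#' (180 degrees minus the D-H-A angle) is strictly below
#' `max_dha_deviation`.
#'
#' @param frame Atom data frame (see [build_planted_scene()]).
#' @param donors Atom ids of donor heavy atoms.
#' @param hydrogens Atom ids of donor-attached hydrogens; each must carry its
#'   parent donor in the frame's `h_parent` column.
#' @param acceptors Atom ids of acceptor atoms.
#' @param criteria A [hbond_criteria()].
#' @return Data frame with columns `donor`, `hydrogen`, `acceptor`,
#'   `da_distance`, `deviation`; zero rows when none found.
#' @export
detect_hbonds <- function(frame, donors, hydrogens, acceptors,
                          criteria = hbond_criteria()) {
  out <- data.frame(donor = integer(0), hydrogen = integer(0),
                    acceptor = integer(0), da_distance = numeric(0),
                    deviation = numeric(0))
  if (length(hydrogens) == 0L || length(acceptors) == 0L) return(out)
  parents <- frame$h_parent[match(hydrogens, frame$id)]
  if (anyNA(parents) || !all(parents %in% donors))
    stop("hydrogen with no donor parent in the supplied donor set")
  Ah <- frame_xyz(frame, acceptors)
  for (k in seq_along(hydrogens)) {
    h <- hydrogens[k]; d <- parents[k]
    Dp <- frame_xyz(frame, d); Hp <- frame_xyz(frame, h)
    ok_a <- acceptors != d
    if (!any(ok_a)) next
    da <- pair_dist(Dp, Ah[ok_a, , drop = FALSE])[1, ]
    hd <- Dp[1, ] - Hp[1, ]
    ha <- sweep(Ah[ok_a, , drop = FALSE], 2, Hp[1, ])
    cosang <- (ha %*% hd) /
      (sqrt(sum(hd^2)) * sqrt(rowSums(ha^2)))
    ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
    dev <- 180 - ang
    hit <- da < criteria$max_da_distance & dev < criteria$max_dha_deviation
    if (any(hit)) {
      aa <- acceptors[ok_a]
      out <- rbind(out, data.frame(donor = d, hydrogen = h,
                                   acceptor = aa[hit],
                                   da_distance = da[hit],
                                   deviation = dev[hit]))
    }
  }
  out
}

## internal: all D-H...A pairs in a frame using role annotations; water
## oxygens act as both donors (via their hydrogens) and acceptors
role_hbond_pairs <- function(frame, criteria) {
  donors <- frame$id[frame$role %in% c("donor", "water_O")]
  hydrogens <- frame$id[frame$role %in% c("donor_H", "water_H")]
  acceptors <- frame$id[frame$role %in% c("acceptor", "water_O")]
  detect_hbonds(frame, donors, hydrogens, acceptors, criteria)
}

#' Count single-water bridges between protein and drug
#'
#' A water bridge is exactly one water molecule simultaneously hydrogen
#' bonded -- in either donor or acceptor role -- to at least one protein atom
#' and at least one drug atom in the same frame.  Chains through two or more
#' waters are not counted.
#'
#' @param frame Atom data frame with roles and `h_parent` links.
#' @param criteria A [hbond_criteria()].
#' @return Integer count of bridging waters.
#' @export
detect_water_bridges <- function(frame, criteria = hbond_criteria()) {
  pairs <- role_hbond_pairs(frame, criteria)
  waters <- frame$id[frame$role == "water_O"]
  if (length(waters) == 0L || nrow(pairs) == 0L) return(0L)
  mol_of <- function(id) frame$molecule[match(id, frame$id)]
  owner_water <- function(id) {
    ## map an atom to its water oxygen (itself, or its parent for water H)
    r <- frame$role[match(id, frame$id)]
    ifelse(r == "water_O", id,
           ifelse(r == "water_H", frame$h_parent[match(id, frame$id)], NA))
  }
  n <- 0L
  for (w in waters) {
    partners <- character(0)
    for (p in seq_len(nrow(pairs))) {
      d <- pairs$donor[p]; a <- pairs$acceptor[p]
      ow_d <- owner_water(d); ow_a <- owner_water(a)
      if (!is.na(ow_d) && ow_d == w && is.na(ow_a))
        partners <- c(partners, mol_of(a))
      if (!is.na(ow_a) && ow_a == w && is.na(ow_d))
        partners <- c(partners, mol_of(d))
    }
    if ("protein" %in% partners && "drug" %in% partners) n <- n + 1L
  }
  n
}

#' Count hydrophobic contact pairs between two apolar selections
#'
#' Cross-molecule apolar heavy-atom pairs with distance strictly below the
#' cutoff.
#'
#' @param frame Atom data frame.
#' @param apolar_protein,apolar_drug Atom ids of the apolar selections; when
#'   `NULL` they default to role `"apolar_C"` atoms of the respective
#'   molecule.
#' @param cutoff Distance cutoff (nm), default 0.45.
#' @return Integer count.
#' @export
count_hydrophobic_pairs <- function(frame, apolar_protein = NULL,
                                    apolar_drug = NULL, cutoff = 0.45) {
  if (is.null(apolar_protein))
    apolar_protein <- frame$id[frame$role == "apolar_C" &
                                 frame$molecule == "protein"]
  if (is.null(apolar_drug))
    apolar_drug <- frame$id[frame$role == "apolar_C" &
                              frame$molecule == "drug"]
  if (length(apolar_protein) == 0L || length(apolar_drug) == 0L) {
    warning("empty apolar selection; returning 0")
    return(0L)
  }
  d <- pair_dist(frame_xyz(frame, apolar_protein),
                 frame_xyz(frame, apolar_drug))
  sum(d < cutoff)
}

#' Count all three interaction types of a frame
#'
#' Role-based convenience wrapper returning the direct hydrogen-bond count
#' between protein and drug, the water-bridge count and the hydrophobic pair
#' count.
#'
#' @inheritParams detect_water_bridges
#' @param hydrophobic_cutoff Cutoff (nm) for [count_hydrophobic_pairs()].
#' @return Named numeric vector `c(hbonds, bridges, hydrophobic)`.
#' @export
count_contacts <- function(frame, criteria = hbond_criteria(),
                           hydrophobic_cutoff = 0.45) {
  pairs <- role_hbond_pairs(frame, criteria)
  mol_of <- function(id) frame$molecule[match(id, frame$id)]
  direct <- 0L
  if (nrow(pairs) > 0L) {
    md <- mol_of(pairs$donor); ma <- mol_of(pairs$acceptor)
    direct <- sum((md == "protein" & ma == "drug") |
                    (md == "drug" & ma == "protein"))
  }
  hyd <- suppressWarnings(
    count_hydrophobic_pairs(frame, cutoff = hydrophobic_cutoff))
  c(hbonds = direct, bridges = detect_water_bridges(frame, criteria),
    hydrophobic = hyd)
}

#' Interaction counts as a function of the control parameter
#'
#' Bins frames by their control-parameter tag (half-open bins, matching the
#' estimator module's convention) and averages the three interaction counts
#' over the frames and realizations falling in each bin.
#'
#' @param frames List of atom data frames.
#' @param lambda Numeric control-parameter tag per frame (nm).
#' @param bins A [make_xi_bins()] result; default 0.025 nm bins over the
#'   lambda range.
#' @param criteria A [hbond_criteria()].
#' @param hydrophobic_cutoff Cutoff (nm).
#' @return Object of class `contact_profile`: data frame with `lam_bin`,
#'   `hbond_counts`, `water_bridge_counts`, `hydrophobic_counts`, `n_frames`
#'   (bins with no frames dropped).
#' @export
profile_vs_lambda <- function(frames, lambda, bins = NULL,
                              criteria = hbond_criteria(),
                              hydrophobic_cutoff = 0.45) {
  stopifnot(length(frames) == length(lambda), length(frames) >= 1L)
  if (is.null(bins)) bins <- make_xi_bins(range(lambda), 0.025)
  bi <- bin_index(lambda, bins)
  if (all(is.na(bi))) stop("no frames fall in any bin")
  counts <- t(vapply(frames, count_contacts, c(hbonds = 0, bridges = 0,
                                               hydrophobic = 0),
                     criteria = criteria,
                     hydrophobic_cutoff = hydrophobic_cutoff))
  keep <- !is.na(bi)
  agg <- rowsum(counts[keep, , drop = FALSE], bi[keep])
  nfr <- as.integer(table(bi[keep]))
  out <- data.frame(lam_bin = bins$centers[as.integer(rownames(agg))],
                    hbond_counts = agg[, "hbonds"] / nfr,
                    water_bridge_counts = agg[, "bridges"] / nfr,
                    hydrophobic_counts = agg[, "hydrophobic"] / nfr,
                    n_frames = nfr)
  rownames(out) <- NULL
  class(out) <- c("contact_profile", "data.frame")
  out
}

#' Mass-weighted radius of gyration
#'
#' @param coords n x 3 coordinate matrix (nm).
#' @param masses Atomic masses (amu); default all equal.
#' @return Mass-weighted RMS distance from the center of mass (nm).
#' @export
radius_of_gyration <- function(coords, masses = NULL) {
  coords <- rbind(coords)
  if (is.null(masses)) masses <- rep(1, nrow(coords))
  stopifnot(length(masses) == nrow(coords))
  if (sum(masses) <= 0) stop("zero total mass")
  com <- colSums(coords * masses) / sum(masses)
  d2 <- rowSums(sweep(coords, 2, com)^2)
  sqrt(sum(masses * d2) / sum(masses))
}

#' Signed dihedral (torsion) angle of four points
#'
#' IUPAC sign convention: looking from p2 towards p3, a clockwise rotation of
#' the far bond is positive.  The planar cis arrangement is 0 degrees, trans
#' is 180.
#'
#' @param p1,p2,p3,p4 Numeric length-3 positions.
#' @return Angle in degrees, in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-12 || sqrt(sum(n2^2)) < 1e-12)
    stop("degenerate dihedral: three consecutive points are collinear")
  x <- sum(n1 * n2)
  y <- sum(cross(n1, n2) * b2) / sqrt(sum(b2^2))
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Torsion time series
#'
#' @param time Times (ps).
#' @param angle Angles (degrees); wrapped into (-180, 180].
#' @param atom_quad Four atom identifiers, metadata.
#' @return Object of class `dihedral_series`.
#' @export
dihedral_series <- function(time, angle, atom_quad = NULL) {
  stopifnot(length(time) == length(angle))
  angle <- ((angle + 180) %% 360) - 180
  angle[angle == -180] <- 180
  structure(list(time = time, angle = angle,
                 atom_quad = atom_quad %||% rep(NA_character_, 4)),
            class = "dihedral_series")
}

#' Circular histogram of a torsion series with peak detection
#'
#' Bins the angles into uniform bins over (-180, 180] and reports local
#' maxima (circular adjacency, strict) whose counts exceed a prominence
#' threshold.
#'
#' @param series A [dihedral_series()] or numeric angle vector (degrees).
#' @param bin_width Bin width (degrees); must divide 360.
#' @param min_peak_fraction A bin is a peak only if its count exceeds this
#'   fraction of the series length (default 0.05).
#' @return List with `centers`, `counts`, `peaks` (centers of peak bins).
#' @export
dihedral_histogram <- function(series, bin_width = 10,
                               min_peak_fraction = 0.05) {
  angle <- if (inherits(series, "dihedral_series")) series$angle else series
  stopifnot(length(angle) >= 1L)
  nb <- round(360 / bin_width)
  if (abs(nb * bin_width - 360) > 1e-9) stop("bin_width must divide 360")
  ## half-open bins (lo, hi], aligned so that -180 is an edge
  idx <- ceiling((angle + 180) / bin_width)
  idx[idx < 1L] <- 1L
  counts <- tabulate(idx, nbins = nb)
  centers <- -180 + bin_width * (seq_len(nb) - 0.5)
  left <- counts[c(nb, seq_len(nb - 1))]
  right <- counts[c(seq_len(nb - 1) + 1, 1)]
  thresh <- min_peak_fraction * length(angle)
  is_peak <- counts > left & counts > right & counts > thresh
  list(centers = centers, counts = counts, peaks = centers[is_peak])
}
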