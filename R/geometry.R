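.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.vnorm <- function(v) sqrt(sum(v^2))

#' Signed dihedral angle of four points
#'
#' IUPAC sign convention: looking from `p2` toward `p3`, a clockwise rotation
#' of the far bond relative to the near bond is positive. Returns degrees in
#' `(-180, 180]`. Degenerate geometry (coincident consecutive points or three
#' collinear consecutive points) is rejected.
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinates (Angstrom)
#' @return signed dihedral in degrees
#' @examples
#' dihedral(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0))  # cis: 0
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (min(.vnorm(b1), .vnorm(b2), .vnorm(b3)) < 1e-9)
    stop("degenerate geometry: coincident consecutive points")
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  if (min(.vnorm(n1), .vnorm(n2)) < 1e-9)
    stop("degenerate geometry: three consecutive points are collinear")
  m <- .cross3(b2 / .vnorm(b2), n1)
  ang <- atan2(sum(m * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

# Place a fourth point from three others and internal coordinates
# (bond length to c, angle b-c-d, torsion a-b-c-d in degrees). Standard
# natural-extension construction; used by the synthetic generators.
.place_dihedral <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  bc <- c - b; bc <- bc / .vnorm(bc)
  ab <- b - a
  n <- .cross3(ab, bc); n <- n / .vnorm(n)
  m <- .cross3(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor), bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Newman-projection regiospecificity assessment
#'
#' Classifies which bond at the alpha carbon is aligned with the radical's
#' singly-occupied p orbital after hydrogen abstraction from the amino group.
#' In the Newman projection along the N-Calpha axis, the remaining N-H is
#' placed at 0 degrees, so the p orbital (perpendicular to the N-H, two-lobe
#' symmetric) lies along the +/-90 degree axis. The leaving bonds project at
#' `phi_NH` (Calpha-Cbeta, since `phi_NH` is the Cbeta-Calpha-N-H dihedral)
#' and `phi_NH + substituent_offset` (Calpha-C of the carboxylate, ideal sp3
#' offset +120 degrees with the sign fixed by L-amino-acid chirality). Each
#' bond's misalignment `omega` is its angular distance to the orbital axis
#' folded to `[0, 90]`: periplanar (<= 30, scission favored), intermediate
#' (30-60, allowed but not optimal), clinal (> 60, unavailable).
#'
#' @param phi_NH signed dihedral Cbeta-Calpha-N-H, degrees
#' @param substituent_offset projection angle from Cbeta to the carboxylate
#'   carbon, degrees; default +120
#' @param boundaries zone boundaries `c(periplanar, intermediate)` on omega,
#'   degrees; default `c(30, 60)`
#' @return an object of class `newman_assessment`: data.frame `bonds` with
#'   `bond`, `projection`, `omega`, `zone`, plus `phi_NH`
#' @examples
#' newman_assess(174.5)   # Calpha-C periplanar, Calpha-Cbeta clinal
#' newman_assess(39.6)    # Calpha-Cbeta intermediate, Calpha-C clinal
#' @export
newman_assess <- function(phi_NH, substituent_offset = 120,
                          boundaries = c(30, 60)) {
  if (!is.finite(phi_NH)) stop("'phi_NH' must be finite")
  fold90 <- function(ang) {
    d <- abs(ang) %% 180
    ifelse(d > 90, 180 - d, d)
  }
  proj <- c("Calpha-Cbeta" = phi_NH,
            "Calpha-C" = phi_NH + substituent_offset)
  omega <- fold90(proj - 90)   # distance to the +/-90 orbital axis
  zone <- ifelse(omega <= boundaries[1], "periplanar",
          ifelse(omega <= boundaries[2], "intermediate", "clinal"))
  structure(list(
    phi_NH = phi_NH,
    bonds = data.frame(bond = names(proj),
                       projection = unname(((proj + 180) %% 360) - 180),
                       omega = unname(omega), zone = unname(zone),
                       stringsAsFactors = FALSE)),
    class = "newman_assessment")
}

#' @export
print.newman_assessment <- function(x, ...) {
  cat(sprintf("Newman assessment at phi(Cb-Ca-N-H) = %.1f deg\n", x$phi_NH))
  for (i in seq_len(nrow(x$bonds)))
    cat(sprintf("  %-13s omega = %5.1f deg -> %s\n",
                x$bonds$bond[i], x$bonds$omega[i], x$bonds$zone[i]))
  invisible(x)
}

# classify a polar partner atom for reporting
.donor_class <- function(elety, resid, elesy) {
  bb_n <- elety == "N"
  hydroxyl <- elety %in% c("OG", "OG1", "OH")
  water <- resid %in% c("HOH", "WAT")
  ifelse(water, "water",
  ifelse(bb_n, "main-chain amide",
  ifelse(hydroxyl, "side-chain hydroxyl",
  ifelse(elesy == "O", "oxygen donor", "nitrogen donor"))))
}

# all pairwise target-centered angles (degrees) between unit vectors in rows of m
.pair_angles <- function(m) {
  n <- nrow(m)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    out[i, j] <- acos(max(-1, min(1, sum(m[i, ] * m[j, ])))) * 180 / pi
  out
}

# square-pyramidal angular test on unit vectors from the target:
# a set of 4 basal vectors has 4 adjacent angles in [70, 110] and 2 trans
# angles >= 140; an apical vector (if any) makes [70, 110] with every basal.
.sqpyr_test <- function(units) {
  n <- nrow(units)
  basal_ok <- function(rows) {
    ang <- .pair_angles(units[rows, , drop = FALSE])
    v <- ang[upper.tri(ang)]
    sum(v >= 70 & v <= 110) == 4L && sum(v >= 140) == 2L
  }
  if (n == 4L) {
    if (basal_ok(1:4)) return("square-pyramidal")
    ang <- .pair_angles(units)
    v <- ang[upper.tri(ang)]
    if (all(v >= 90 & v <= 130)) return("tetrahedral-like")
    return("irregular")
  }
  if (n == 5L) {
    for (ap in 1:5) {
      rows <- setdiff(1:5, ap)
      if (!basal_ok(rows)) next
      apang <- vapply(rows, function(i)
        acos(max(-1, min(1, sum(units[ap, ] * units[i, ])))) * 180 / pi, 0)
      if (all(apang >= 70 & apang <= 110)) return("square-pyramidal")
    }
    return("irregular")
  }
  if (n <= 2L) "underdetermined" else "irregular"
}

#' Polar-contact census around a target atom
#'
#' Lists all nitrogen/oxygen atoms within `cutoff` of the target (excluding
#' the target's own residue and, by default, hydrogens), and classifies the
#' contact geometry. "Square-pyramidal" requires 4-5 contacts passing the
#' angular test: four basal donors with adjacent basal-target-basal angles in
#' [70, 110] degrees (and the two trans angles >= 140), plus, when a fifth
#' partner exists, basal-target-apical angles in [70, 110].
#'
#' @param struct a [structure3d()]
#' @param target an atom selector (`"chain:resnum[:icode]:atomname"`)
#' @param cutoff contact distance cutoff, Angstrom; default 3.5
#' @return an object of class `contact_census`
#' @export
contact_census <- function(struct, target, cutoff = 3.5) {
  stopifnot(inherits(struct, "structure3d"))
  rows <- atom_select(struct, target)
  if (length(rows) == 0L) stop("selector '", target, "' matches no atom")
  if (length(rows) > 1L)
    stop("ambiguous selector '", target, "': matches atoms ",
         paste(struct$atom$eleno[rows], collapse = ", "))
  a <- struct$atom
  t_xyz <- as.numeric(a[rows, c("x", "y", "z")])
  same_res <- a$chain == a$chain[rows] & a$resno == a$resno[rows] &
    a$insert == a$insert[rows]
  cand <- which(!same_res & a$elesy %in% c("N", "O"))
  if (length(cand)) {
    d <- sqrt((a$x[cand] - t_xyz[1])^2 + (a$y[cand] - t_xyz[2])^2 +
              (a$z[cand] - t_xyz[3])^2)
    keep <- d <= cutoff
    cand <- cand[keep]; d <- d[keep]
    o <- order(d)
    cand <- cand[o]; d <- d[o]
  } else d <- numeric()
  contacts <- data.frame(
    eleno = a$eleno[cand], elety = a$elety[cand], resid = a$resid[cand],
    chain = a$chain[cand], resno = a$resno[cand],
    distance = d,
    donor_class = .donor_class(a$elety[cand], a$resid[cand], a$elesy[cand]),
    stringsAsFactors = FALSE)
  geometry <- if (nrow(contacts) == 0L) "underdetermined" else {
    units <- sweep(.xyz(struct, cand), 2, t_xyz)
    units <- units / sqrt(rowSums(units^2))
    .sqpyr_test(units)
  }
  structure(list(target = target, target_row = rows,
                 contacts = contacts, geometry = geometry, cutoff = cutoff),
            class = "contact_census")
}

#' @export
print.contact_census <- function(x, ...) {
  cat(sprintf("Contact census for %s (cutoff %.2f A): %d polar contacts, %s\n",
              x$target, x$cutoff, nrow(x$contacts), x$geometry))
  if (nrow(x$contacts))
    print(x$contacts[, c("elety", "resid", "chain", "resno", "distance",
                         "donor_class")], row.names = FALSE)
  invisible(x)
}

# Kabsch least-squares rotation (proper, det = +1) of centered P onto Q
.kabsch <- function(P, Q) {
  C <- crossprod(P, Q)
  sv <- svd(C)
  s <- sign(det(sv$u) * det(sv$v))
  sv$u %*% diag(c(1, 1, s)) %*% t(sv$v)
}

#' Rigid least-squares superposition with optional outlier trimming
#'
#' Superposes paired coordinate sets by the Kabsch algorithm (proper rotation
#' only; reflections are resolved to det = +1). With `trim = TRUE`, pairs
#' deviating by more than twice the current RMSD are dropped and the fit
#' repeated, until nothing changes or 70 percent of the pairs would be lost.
#' Structures are paired on Calpha atoms by (chain, residue number,
#' insertion code).
#'
#' @param ref,mov paired `n x 3` coordinate matrices, or two [structure3d()]
#' @param trim iteratively drop outlier pairs; default FALSE
#' @param atoms atom name used to pair two structures; default `"CA"`
#' @return an object of class `superposition`: `rotation` (3 x 3, applied to
#'   the centered moving set), `translation`, `rmsd`, `n_used`, `n_total`,
#'   `rounds`, `used` (logical vector over pairs)
#' @export
superpose <- function(ref, mov, trim = FALSE, atoms = "CA") {
  if (inherits(ref, "structure3d") && inherits(mov, "structure3d")) {
    ka <- with(ref$atom, paste(chain, resno, insert))[ref$atom$elety == atoms]
    kb <- with(mov$atom, paste(chain, resno, insert))[mov$atom$elety == atoms]
    common <- intersect(ka, kb)
    if (length(common) < 3L) stop("fewer than 3 paired ", atoms, " atoms")
    ra <- which(ref$atom$elety == atoms)[match(common, ka)]
    rb <- which(mov$atom$elety == atoms)[match(common, kb)]
    ref <- .xyz(ref, ra); mov <- .xyz(mov, rb)
  }
  ref <- as.matrix(ref); mov <- as.matrix(mov)
  if (!all(dim(ref) == dim(mov)) || ncol(ref) != 3L)
    stop("'ref' and 'mov' must be equal-size n x 3 matrices")
  n_total <- nrow(ref)
  if (n_total < 3L) stop("need >= 3 paired atoms")
  used <- rep(TRUE, n_total)
  rounds <- 0L
  repeat {
    cr <- colMeans(ref[used, , drop = FALSE])
    cm <- colMeans(mov[used, , drop = FALSE])
    R <- .kabsch(sweep(mov[used, , drop = FALSE], 2, cm),
                 sweep(ref[used, , drop = FALSE], 2, cr))
    dev_all <- sqrt(rowSums((sweep(mov, 2, cm) %*% R -
                             sweep(ref, 2, cr))^2))
    rmsd <- sqrt(mean(dev_all[used]^2))
    if (!trim) break
    drop_new <- used & dev_all > 2 * rmsd
    if (!any(drop_new)) break
    if (sum(used) - sum(drop_new) < ceiling(0.7 * n_total)) {
      # respect the retention floor: drop only the worst offenders
      k <- sum(used) - ceiling(0.7 * n_total)
      if (k <= 0L) break
      worst <- order(-dev_all * used)[seq_len(k)]
      used[worst] <- FALSE
    } else used[drop_new] <- FALSE
    rounds <- rounds + 1L
  }
  structure(list(rotation = R, translation = cr - as.numeric(cm %*% R),
                 rmsd = rmsd, n_used = sum(used), n_total = n_total,
                 rounds = rounds, used = used),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("Superposition: rmsd = %.4f A over %d/%d pairs (%d trimming rounds)\n",
              x$rmsd, x$n_used, x$n_total, x$rounds))
  invisible(x)
}

.gamma_atom <- function(resid) {
  switch(resid,
         SER = "OG", THR = "OG1", CYS = "SG", VAL = "CG1", ILE = "CG1",
         "CG")
}

#' Side-chain chi1 rotation between two structures
#'
#' Absolute difference of the chi1 dihedral (N-CA-CB-gamma atom) of one
#' residue in two structures, folded to `[0, 180]` degrees. This is the
#' quantity behind statements like "a ~110 degree rotation of the serine
#' side-chain" between liganded and unliganded models.
#'
#' @param structA,structB two [structure3d()]
#' @param chain chain identifier
#' @param resno residue number
#' @param icode insertion code; default `""`
#' @return the folded rotation in degrees, with attribute `chi1` giving the
#'   two signed dihedrals
#' @export
chi1_delta <- function(structA, structB, chain, resno, icode = "") {
  chi1_of <- function(struct, label) {
    a <- struct$atom
    res <- a$chain == chain & a$resno == resno & a$insert == icode
    if (!any(res)) stop("residue ", chain, ":", resno, " absent in ", label)
    resid <- a$resid[res][1]
    gamma <- .gamma_atom(resid)
    pos <- lapply(c("N", "CA", "CB", gamma), function(nm) {
      i <- which(res & a$elety == nm)
      if (!length(i))
        stop("residue ", chain, ":", resno, " (", resid, ") in ", label,
             " is missing atom ", nm)
      as.numeric(a[i[1], c("x", "y", "z")])
    })
    dihedral(pos[[1]], pos[[2]], pos[[3]], pos[[4]])
  }
  c1 <- chi1_of(structA, "structA")
  c2 <- chi1_of(structB, "structB")
  d <- abs(c1 - c2) %% 360
  out <- if (d > 180) 360 - d else d
  attr(out, "chi1") <- c(A = c1, B = c2)
  out
}
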