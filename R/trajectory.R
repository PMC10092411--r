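# Pair-geometry extraction from trajectory frames and instantaneous
# FRET-efficiency traces.
#
# A geometry trajectory is a data frame of class "geometry_frames" with
# columns time_ps, refD[xyz], refA[xyz], muD[xyz], muA[xyz]: per frame,
# the two chromophore reference points (nm) and unit transition-dipole
# vectors. File dialect: whitespace-separated columns after a header
# line "# time_ps refDx ... muAz"; units fixed at nm / ps.

.GEOM_COLS <- c("time_ps",
                "refDx", "refDy", "refDz", "refAx", "refAy", "refAz",
                "muDx", "muDy", "muDz", "muAx", "muAy", "muAz")

#' Assemble geometry frames from columns
#'
#' @param time_ps frame times, ps, non-decreasing.
#' @param ref_D,ref_A n x 3 matrices of chromophore reference points, nm.
#' @param mu_D,mu_A n x 3 matrices of transition-dipole directions;
#'   normalized to unit length on construction (an error if any norm
#'   deviates from 1 by more than 10%).
#' @return `geometry_frames` data frame.
#' @export
geometry_frames <- function(time_ps, ref_D, ref_A, mu_D, mu_A) {
  ref_D <- as.matrix(ref_D); ref_A <- as.matrix(ref_A)
  mu_D <- as.matrix(mu_D); mu_A <- as.matrix(mu_A)
  n <- length(time_ps)
  for (m in list(ref_D, ref_A, mu_D, mu_A))
    if (!all(dim(m) == c(n, 3L))) stop("all fields must be n x 3 for n frames")
  if (is.unsorted(time_ps)) stop("frame times must be non-decreasing")
  for (nmu in c("mu_D", "mu_A")) {
    m <- get(nmu)
    nrm <- sqrt(rowSums(m^2))
    if (any(abs(nrm - 1) > 0.10))
      stop(nmu, " deviates from unit length by more than 10% in frame(s) ",
           paste(utils::head(which(abs(nrm - 1) > 0.10), 5), collapse = ", "))
    # renormalize only when measurably off unit length, so unit input
    # (and file round-trips) stay bit-identical
    off <- abs(nrm - 1) > 1e-9
    m[off, ] <- m[off, , drop = FALSE] / nrm[off]
    assign(nmu, m)
  }
  out <- data.frame(time_ps = as.numeric(time_ps),
                    refDx = ref_D[, 1], refDy = ref_D[, 2], refDz = ref_D[, 3],
                    refAx = ref_A[, 1], refAy = ref_A[, 2], refAz = ref_A[, 3],
                    muDx = mu_D[, 1], muDy = mu_D[, 2], muDz = mu_D[, 3],
                    muAx = mu_A[, 1], muAy = mu_A[, 2], muAz = mu_A[, 3])
  class(out) <- c("geometry_frames", "data.frame")
  out
}

#' Read / write a geometry-table trajectory
#'
#' Plain-text dialect: one header line starting with `#` listing the 13
#' column names, then whitespace-separated floats, one frame per row.
#' Units are fixed (ps, nm). Gzip-compressed files are read
#' transparently.
#'
#' @param path file path.
#' @return `read_geometry_table` returns [geometry_frames()];
#'   `write_geometry_table` returns the path invisibly.
#' @export
read_geometry_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#"))
    stop("geometry table must start with a '# time_ps ...' header line")
  header <- strsplit(sub("^#\\s*", "", first), "\\s+")[[1]]
  if (!identical(header, .GEOM_COLS))
    stop("unexpected geometry-table header; expected: # ",
         paste(.GEOM_COLS, collapse = " "))
  tab <- tryCatch(
    utils::read.table(path, comment.char = "#", col.names = .GEOM_COLS,
                      colClasses = "numeric"),
    error = function(e) stop("malformed geometry table: ", conditionMessage(e))
  )
  if (anyNA(tab)) {
    bad <- which(rowSums(is.na(tab)) > 0)[1]
    stop("malformed geometry table row ", bad + 1L, " in ", path)
  }
  geometry_frames(tab$time_ps,
                  as.matrix(tab[, 2:4]), as.matrix(tab[, 5:7]),
                  as.matrix(tab[, 8:10]), as.matrix(tab[, 11:13]))
}

#' @rdname read_geometry_table
#' @param frames [geometry_frames()].
#' @export
write_geometry_table <- function(frames, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste("#", paste(.GEOM_COLS, collapse = " ")), con)
  utils::write.table(format(as.data.frame(frames), digits = 17,
                            scientific = TRUE, trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Define a chromophore within an atomistic structure
#'
#' @param atoms integer indices of the chromophore's atoms.
#' @param masses atomic masses, same length as `atoms`.
#' @param dipole_axis ordered pair of atom indices (members of `atoms`)
#'   whose difference vector defines the transition-dipole direction.
#' @return object of class `chromophore_def`.
#' @export
chromophore_def <- function(atoms, masses, dipole_axis) {
  if (length(atoms) < 2L) stop("a chromophore needs >= 2 atoms")
  if (length(masses) != length(atoms)) stop("one mass per atom required")
  if (length(dipole_axis) != 2L || !all(dipole_axis %in% atoms))
    stop("dipole_axis must be two atom indices belonging to the chromophore")
  structure(list(atoms = as.integer(atoms), masses = as.numeric(masses),
                 dipole_axis = as.integer(dipole_axis)),
            class = "chromophore_def")
}

#' Geometry frames from atomistic coordinates
#'
#' The reference point of each chromophore is the coordinate of the atom
#' nearest its mass center, and the dipole direction is the normalized
#' vector between the two configured axis atoms.
#'
#' @param coords numeric array n_frames x n_atoms x 3, nm.
#' @param time_ps frame times, ps.
#' @param chrom_D,chrom_A [chromophore_def()] for donor and acceptor.
#' @return [geometry_frames()].
#' @export
frames_from_coordinates <- function(coords, time_ps, chrom_D, chrom_A) {
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop("coords must be an n_frames x n_atoms x 3 array")
  n <- dim(coords)[1]
  one <- function(cd, f) {
    xyz <- coords[f, cd$atoms, , drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    com <- colSums(xyz * cd$masses) / sum(cd$masses)
    d2 <- rowSums(sweep(xyz, 2, com)^2)
    ref <- xyz[which.min(d2), ]
    ax <- coords[f, cd$dipole_axis[2], ] - coords[f, cd$dipole_axis[1], ]
    list(ref = ref, mu = unit_vector(ax))
  }
  refD <- matrix(0, n, 3); refA <- matrix(0, n, 3)
  muD <- matrix(0, n, 3); muA <- matrix(0, n, 3)
  for (f in seq_len(n)) {
    gd <- one(chrom_D, f); ga <- one(chrom_A, f)
    refD[f, ] <- gd$ref; muD[f, ] <- gd$mu
    refA[f, ] <- ga$ref; muA[f, ] <- ga$mu
  }
  geometry_frames(time_ps, refD, refA, muD, muA)
}

#' Pair geometry of a single frame
#'
#' Distance R_DA, Forster angles and the orientation factor of one
#' geometry frame (or row index of a trajectory).
#'
#' @param frame one-row [geometry_frames()] (or a full trajectory with
#'   `row` selecting the frame).
#' @param row frame index, default 1.
#' @return one-row data frame: `R_DA` (nm), `theta_D`, `theta_A`, `phi`
#'   (radians), `kappa2`.
#' @export
pair_geometry <- function(frame, row = 1L) {
  f <- frame[row, , drop = FALSE]
  rD <- c(f$refDx, f$refDy, f$refDz)
  rA <- c(f$refAx, f$refAy, f$refAz)
  if (all(rD == rA)) stop("coincident chromophore reference points")
  kv <- kappa_squared_vectors(c(f$muDx, f$muDy, f$muDz),
                              c(f$muAx, f$muAy, f$muAz),
                              rA - rD)
  kv$geometry
}

# Vectorized geometry over all frames (internal fast path).
all_pair_geometry <- function(frames) {
  R <- cbind(frames$refAx - frames$refDx,
             frames$refAy - frames$refDy,
             frames$refAz - frames$refDz)
  Rn <- sqrt(rowSums(R^2))
  if (any(Rn == 0)) stop("coincident chromophore reference points in frame(s) ",
                         paste(utils::head(which(Rn == 0), 5), collapse = ", "))
  Rh <- R / Rn
  muD <- cbind(frames$muDx, frames$muDy, frames$muDz)
  muA <- cbind(frames$muAx, frames$muAy, frames$muAz)
  dR <- rowSums(muD * Rh)
  aR <- rowSums(muA * Rh)
  kap <- rowSums(muD * muA) - 3 * dR * aR
  data.frame(R_DA = Rn,
             theta_D = acos(pmin(1, pmax(-1, dR))),
             theta_A = acos(pmin(1, pmax(-1, aR))),
             kappa2 = kap^2)
}

#' Instantaneous FRET-efficiency trace
#'
#' For each frame the instantaneous efficiency is computed from the
#' instantaneous distance R_DA(t) and, under the default dynamic-kappa2
#' policy, the instantaneous orientation factor kappa2(t) entering the
#' Forster radius R0(t). With a fixed kappa2 in `params`, R0 is constant
#' and only the distance varies.
#'
#' @param frames [geometry_frames()].
#' @param params [forster_pair_params()].
#' @return object of class `fret_trace`: data frame with `time_ps`,
#'   `R_DA`, `kappa2`, `efficiency`, and attributes `params` and
#'   `mean_efficiency`.
#' @export
fret_trace <- function(frames, params) {
  if (nrow(frames) == 0L) stop("empty trajectory")
  if (!inherits(params, "forster_pair_params"))
    stop("params must be forster_pair_params")
  g <- all_pair_geometry(frames)
  dynamic <- identical(params$kappa2, "dynamic")
  k2 <- if (dynamic) g$kappa2 else rep(params$kappa2, nrow(g))
  R0 <- (.FORSTER_PREFACTOR_NM6 * k2 * params$phiD0 * params$J /
           params$n^4)^(1 / 6)
  eff <- fret_efficiency(g$R_DA, R0)
  out <- data.frame(time_ps = frames$time_ps, R_DA = g$R_DA,
                    kappa2 = k2, efficiency = eff)
  attr(out, "params") <- params
  attr(out, "mean_efficiency") <- mean(eff)
  class(out) <- c("fret_trace", "data.frame")
  out
}

#' @export
print.fret_trace <- function(x, ...) {
  cat(sprintf(
    "<fret_trace: %d frames, %.0f-%.0f ps, mean E = %.3f, mean R_DA = %.3f nm>\n",
    nrow(x), min(x$time_ps), max(x$time_ps),
    attr(x, "mean_efficiency"), mean(x$R_DA)))
  invisible(x)
}

#' Histogram of instantaneous efficiencies
#'
#' Counts over `n_bins` equal-width bins spanning \[0, 1\]; the right
#' edge of the last bin is closed so E = 1 is counted.
#'
#' @param trace [fret_trace()].
#' @param n_bins number of bins (>= 1).
#' @return data frame `bin_low`, `bin_high`, `count`.
#' @export
efficiency_histogram <- function(trace, n_bins = 50L) {
  if (n_bins < 1L) stop("n_bins must be >= 1")
  edges <- seq(0, 1, length.out = n_bins + 1L)
  idx <- pmin(pmax(findInterval(trace$efficiency, edges,
                                rightmost.closed = TRUE), 1L), n_bins)
  data.frame(bin_low = edges[-length(edges)], bin_high = edges[-1],
             count = tabulate(idx, nbins = n_bins))
}

#' Distance-stratified mean efficiencies
#'
#' Frames are classified by interchromophoric distance into
#' `R_DA <= e1`, `e1 < R_DA < e2`, ..., `R_DA >= e_last` (boundary
#' frames belong to the closed outer classes), and the mean efficiency
#' is reported per class. An empty class has mean `NA`, not 0. The
#' count-weighted mean of the class means reproduces the overall mean.
#'
#' @param trace [fret_trace()].
#' @param edges strictly increasing class edges, nm (default `c(1, 2)`).
#' @return data frame with `class`, `n_frames`, `mean_efficiency`, plus
#'   attribute `overall_mean`.
#' @export
stratify_by_distance <- function(trace, edges = c(1, 2)) {
  if (any(diff(edges) <= 0)) stop("edges must be strictly increasing")
  ne <- length(edges)
  labels <- c(sprintf("R_DA <= %g", edges[1]),
              if (ne > 1)
                sprintf("%g < R_DA < %g", edges[-ne], edges[-1]),
              sprintf("R_DA >= %g", edges[ne]))
  # boundary values fall in the closed outer classes, interior strict
  cls <- findInterval(trace$R_DA, edges) + 1L
  cls[trace$R_DA == edges[1]] <- 1L
  cnt <- tabulate(cls, nbins = ne + 1L)
  mns <- vapply(seq_len(ne + 1L), function(i)
    if (cnt[i] == 0L) NA_real_ else mean(trace$efficiency[cls == i]),
    numeric(1))
  out <- data.frame(class = labels, n_frames = cnt, mean_efficiency = mns)
  attr(out, "overall_mean") <- mean(trace$efficiency)
  out
}

#' Extract a time window of a trace
#'
#' @param trace [fret_trace()].
#' @param t_start,t_end window bounds, ps (closed interval,
#'   `t_start < t_end`). An empty window gives an empty trace.
#' @return [fret_trace()] with original times preserved.
#' @export
window_extract <- function(trace, t_start, t_end) {
  if (t_start >= t_end) stop("t_start must be < t_end")
  keep <- trace$time_ps >= t_start & trace$time_ps <= t_end
  out <- trace[keep, , drop = FALSE]
  attr(out, "params") <- attr(trace, "params")
  attr(out, "mean_efficiency") <-
    if (any(keep)) mean(out$efficiency) else NA_real_
  class(out) <- class(trace)
  out
}
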