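#' Per-atom chi matrix over an ensemble
#'
#' Builds one neighborhood and projection per requested atom and evaluates
#' the chi series for each. Atoms whose neighborhood is degenerate,
#' collinear, or ill-conditioned are skipped with a warning and returned as
#' NA rows, so downstream aggregates can carry an explicit missing marker.
#'
#' @param ref a [as_reference()] object.
#' @param ens a [as_ensemble()] object.
#' @param atoms atom indices to analyse (default: all heavy atoms).
#' @param radius,k,heavy_only,min_size passed to [build_neighborhood()].
#' @param max_cond passed to [build_projection()].
#' @return a `nap_chimat`: atoms x frames matrix of chi (Angstrom^2) with
#'   rownames the atom indices; attribute `failed` lists skipped atoms.
#' @export
chi_matrix <- function(ref, ens, atoms = which(ref$heavy), radius = NULL,
                       k = NULL, heavy_only = TRUE, min_size = 10L,
                       max_cond = 1e8) {
  out <- matrix(NA_real_, length(atoms), ens$nframes,
                dimnames = list(atoms, NULL))
  failed <- integer(0)
  for (ii in seq_along(atoms)) {
    res <- try({
      nb <- build_neighborhood(ref, atoms[ii], radius = radius, k = k,
                               heavy_only = heavy_only, min_size = min_size)
      P <- build_projection(nb, max_cond = max_cond)
      chi_series(ref, ens, nb, P)
    }, silent = TRUE)
    if (inherits(res, "try-error")) failed <- c(failed, atoms[ii])
    else out[ii, ] <- res
  }
  if (length(failed)) {
    warning(length(failed), " atom(s) skipped (degenerate/ill-conditioned ",
            "neighborhoods): ", paste(utils::head(failed, 10L),
                                      collapse = ", "),
            if (length(failed) > 10L) ", ...")
  }
  structure(out, class = c("nap_chimat", "matrix"), failed = failed,
            atoms = atoms)
}

#' Selection-averaged chi time series
#'
#' The chi profile of a region: per frame, chi averaged over the heavy
#' atoms of a selection (the convention used for helix-level NAP-vs-time
#' profiles tracking gate opening).
#'
#' @param ref,ens,atoms,... as in [chi_matrix()]; `atoms` is typically a
#'   [select_atoms()] result. A precomputed [chi_matrix()] can be passed as
#'   `cm` instead.
#' @param cm optional precomputed chi matrix for `atoms`.
#' @return numeric vector of length `ens$nframes`.
#' @export
chi_timeseries <- function(ref, ens, atoms, cm = NULL, ...) {
  atoms <- atoms[ref$heavy[atoms]]
  if (!length(atoms)) stop("selection has no heavy atoms")
  if (is.null(cm)) cm <- chi_matrix(ref, ens, atoms, ...)
  ok <- stats::complete.cases(cm)
  if (!any(ok)) stop("all neighborhoods in the selection are degenerate")
  colMeans(cm[ok, , drop = FALSE])
}

#' Per-site ensemble statistics of chi
#'
#' Mean chi and the NAP susceptibility \eqn{\langle(\chi -
#' \langle\chi\rangle)^2\rangle} per site, with the population (1/T)
#' variance convention matching the ensemble-average notation. Sites with
#' missing series yield NA rows.
#'
#' @param cm a [chi_matrix()] (sites x frames), or any numeric matrix of
#'   per-site chi series.
#' @param gaps optional per-site spectral gap values to attach.
#' @return data.frame with columns `site`, `mean_chi`, `susceptibility`,
#'   `gap`, `n_frames`.
#' @export
site_statistics <- function(cm, gaps = NULL) {
  cm <- as.matrix(cm)
  Tn <- ncol(cm)
  if (Tn < 2L) stop("need at least 2 frames")
  mu <- rowMeans(cm)
  susc <- rowMeans((cm - mu)^2)
  data.frame(site = if (!is.null(rownames(cm))) rownames(cm)
             else seq_len(nrow(cm)),
             mean_chi = mu, susceptibility = susc,
             gap = if (is.null(gaps)) NA_real_ else gaps,
             n_frames = Tn, row.names = NULL)
}

#' Residue-level chi series
#'
#' Residue chi at each frame is the mean over that residue's analysed
#' heavy atoms (skipping atoms with missing series).
#'
#' @param ref a [as_reference()] object.
#' @param cm a [chi_matrix()] over some atoms of `ref`.
#' @return a residues x frames matrix; rownames "chain:resid"; attributes
#'   `resid`, `chain`.
#' @export
residue_chi <- function(ref, cm) {
  atoms <- attr(cm, "atoms")
  ok <- stats::complete.cases(cm)
  key <- paste(ref$chain[atoms], ref$resid[atoms], sep = ":")
  keys <- unique(key)
  out <- matrix(NA_real_, length(keys), ncol(cm),
                dimnames = list(keys, NULL))
  for (kk in seq_along(keys)) {
    rows <- which(key == keys[kk] & ok)
    if (length(rows)) out[kk, ] <- colMeans(cm[rows, , drop = FALSE])
  }
  parts <- strsplit(keys, ":")
  structure(out,
            resid = as.integer(vapply(parts, `[`, "", 2L)),
            chain = vapply(parts, `[`, "", 1L))
}

#' Residue-residue NAP covariance map
#'
#' Same-time covariance \eqn{\langle(\chi_i - \langle\chi_i\rangle)(\chi_j
#' - \langle\chi_j\rangle)\rangle} between residue-level chi series
#' (population 1/T convention). The diagonal equals the residue NAP
#' susceptibility bit-exactly. Large off-diagonal entries between spatially
#' distant residues are the allosteric-pair signal.
#'
#' @param rc a [residue_chi()] matrix (or any sites x frames matrix with
#'   attributes `resid`, `chain`).
#' @param normalize also return the Pearson-normalized map (default FALSE,
#'   covariance is primary).
#' @return a `nap_cormap`: list with `cov` (symmetric matrix), `resid`,
#'   `chain`, `n_frames`, and `cor` if requested.
#' @export
correlation_map <- function(rc, normalize = FALSE) {
  keep <- stats::complete.cases(rc)
  X <- rc[keep, , drop = FALSE]
  if (nrow(X) < 2L) stop("need at least 2 residues with valid series")
  if (ncol(X) < 2L) stop("need at least 2 frames")
  Xc <- X - rowMeans(X)
  cv <- tcrossprod(Xc) / ncol(X)
  cv <- (cv + t(cv)) / 2
  # same arithmetic path as site_statistics, so the diagonal equals the
  # per-residue susceptibility bit-exactly
  diag(cv) <- rowMeans(Xc^2)
  out <- list(cov = cv,
              resid = attr(rc, "resid")[keep],
              chain = attr(rc, "chain")[keep],
              n_frames = ncol(X))
  if (normalize) {
    s <- sqrt(diag(cv))
    out$cor <- cv / outer(s, s)
  }
  class(out) <- "nap_cormap"
  out
}

#' @export
print.nap_cormap <- function(x, ...) {
  cat("nap_cormap:", nrow(x$cov), "residues x", x$n_frames,
      "frames | max off-diagonal cov =",
      format(max(x$cov[upper.tri(x$cov)]), digits = 4), "\n")
  invisible(x)
}

# reference Calpha (or centroid) position of each residue in a cormap
.residue_anchor <- function(map, ref) {
  t(vapply(seq_along(map$resid), function(k) {
    idx <- which(ref$resid == map$resid[k] & ref$chain == map$chain[k])
    ca <- idx[ref$atom_name[idx] == "CA"]
    if (length(ca)) ref$xyz[ca[1], ] else colMeans(ref$xyz[idx, , drop = FALSE])
  }, numeric(3)))
}

#' Supra-threshold, spatially distant residue pairs
#'
#' Candidate allosteric pairs: off-diagonal covariances larger than
#' `fraction` of the maximum off-diagonal value (default 4 percent),
#' restricted to pairs at sequence separation of at least `min_seq_sep`
#' residues and reference Calpha-Calpha (centroid when no CA atom exists)
#' distance of at least `min_distance` — spatially adjacent residues are
#' trivially correlated by direct contact and are filtered out. Pairs on
#' different chains pass the sequence-separation filter automatically.
#'
#' @param map a [correlation_map()] object.
#' @param ref the [as_reference()] object (for anchor distances).
#' @param fraction threshold as a fraction of the off-diagonal maximum,
#'   in (0, 1); default 0.04.
#' @param min_seq_sep minimum |resid_i - resid_j| (default 10).
#' @param min_distance minimum anchor distance in Angstrom (default 12).
#' @return data.frame ranked by decreasing covariance: `resid_i`,
#'   `chain_i`, `resid_j`, `chain_j`, `covariance`, `distance`, `seq_sep`.
#'   May be empty.
#' @export
threshold_pairs <- function(map, ref, fraction = 0.04, min_seq_sep = 10L,
                            min_distance = 12) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  cv <- map$cov
  nr <- nrow(cv)
  ut <- which(upper.tri(cv), arr.ind = TRUE)
  thr <- fraction * max(cv[upper.tri(cv)])
  anchors <- .residue_anchor(map, ref)
  i <- ut[, 1]; j <- ut[, 2]
  seq_sep <- ifelse(map$chain[i] == map$chain[j],
                    abs(map$resid[i] - map$resid[j]), Inf)
  dist <- sqrt(rowSums((anchors[i, , drop = FALSE] -
                        anchors[j, , drop = FALSE])^2))
  keep <- cv[ut] > thr & seq_sep >= min_seq_sep & dist >= min_distance
  out <- data.frame(resid_i = map$resid[i], chain_i = map$chain[i],
                    resid_j = map$resid[j], chain_j = map$chain[j],
                    covariance = cv[ut], distance = dist,
                    seq_sep = seq_sep)[keep, , drop = FALSE]
  out <- out[order(-out$covariance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mean all-pairs distance between two selections
#'
#' Averages the Euclidean distance over every cross pair of the two
#' (heavy-atom) selections in one frame — the inter-helix distance
#' diagnostic paired with chi profiles in gate-opening analyses.
#'
#' @param frame N x 3 coordinate matrix (see [frame_coords()]).
#' @param selA,selB atom index vectors (non-empty, disjoint selections).
#' @return mean distance in Angstrom.
#' @export
interhelix_distance <- function(frame, selA, selB) {
  if (!length(selA) || !length(selB)) stop("empty selection")
  A <- frame[selA, , drop = FALSE]
  B <- frame[selB, , drop = FALSE]
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  mean(sqrt(pmax(d2, 0)))
}

#' Per-frame inter-selection distance series
#' @param ens a [as_ensemble()] object.
#' @param selA,selB as in [interhelix_distance()].
#' @export
interhelix_series <- function(ens, selA, selB) {
  vapply(seq_len(ens$nframes),
         function(t) interhelix_distance(frame_coords(ens, t), selA, selB),
         numeric(1))
}

#' Rescale susceptibilities to the 0-100 hotspot colour scale
#'
#' Min-max rescaling of per-residue susceptibility to [0, 100] (blue 0 to
#' red 100), the scale written into the B-factor column for structure
#' colouring. All-equal input maps to all zeros by convention. NA
#' (missing-neighborhood) sites stay NA. The rescaling is monotone, so
#' residue ranking is preserved.
#'
#' @param susceptibility numeric vector (>= 1 finite value required).
#' @return numeric vector in [0, 100].
#' @export
hotspot_scale <- function(susceptibility) {
  v <- susceptibility
  ok <- is.finite(v)
  if (!any(ok)) stop("no valid susceptibility values")
  rng <- range(v[ok])
  if (diff(rng) == 0) {
    message("all susceptibilities equal; hotspot scale set to 0")
    v[ok] <- 0
    return(v)
  }
  v[ok] <- 100 * (v[ok] - rng[1]) / diff(rng)
  v
}
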