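# Readers and writers for alpha-carbon traces.
#
# PDB parsing is delegated to bio3d; this layer only selects the trace
# (one CA per residue, first NMR model by default), keeps the
# non-typical residues that are part of the polypeptide (MSE and
# friends), and records numbering gaps as machine-readable breaks.

# Residues with non-standard names that must be retained as chain
# members rather than dropped as ligands.
NONSTANDARD_RESIDUES <- c(
  "MSE", "FGL", "LLP", "SAC", "SER", "PCA", "MEN", "CSB", "HTR", "PTR",
  "TYR", "SCE", "M3L", "OCS", "KCX", "SEB", "MLY", "CSW", "TPO", "SEP",
  "AYA", "TRN"
)

#' Read an alpha-carbon trace from a PDB file
#'
#' Extracts one vertex per residue possessing an alpha-carbon atom.
#' HETATM records of modified amino acids (e.g. MSE selenomethionine)
#' are retained as chain members so that no artificial breaks are
#' introduced. For multi-model (NMR) files the first model is used
#' unless another is requested. Alternate locations keep the blank or
#' 'A' indicator. Residues without an alpha-carbon are skipped with a
#' warning; the resulting numbering gap is recorded as a break.
#'
#' @param path path to a PDB file.
#' @param chain_id chain identifier; default the first chain in the file.
#' @param model model number (1-based); default 1.
#' @return a [new_chain()] object.
#' @export
read_pdb_chain <- function(path, chain_id = NULL, model = 1L) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atoms <- pdb$atom
  if (is.null(chain_id)) chain_id <- atoms$chain[1L]
  in_chain <- !is.na(atoms$chain) & atoms$chain == chain_id
  if (!any(in_chain))
    stop(sprintf("chain not found: '%s' in %s", chain_id, path))

  alt_ok <- is.na(atoms$alt) | atoms$alt %in% c("", "A")
  is_ca <- atoms$elety == "CA" & in_chain & alt_ok
  # guard against calcium ions, whose atom name is also CA
  if ("elesy" %in% names(atoms)) {
    elem <- atoms$elesy
    is_ca <- is_ca & (is.na(elem) | elem != "CA")
  }
  is_ca <- is_ca & atoms$resid != "CA"
  idx <- which(is_ca)
  if (length(idx) == 0L)
    stop(sprintf("chain '%s' has no alpha-carbon atoms", chain_id))

  # one CA per residue (file order; first wins if altloc slipped through)
  reskey <- paste(atoms$resno[idx], atoms$insert[idx])
  idx <- idx[!duplicated(reskey)]

  # warn about residues present in the chain but lacking a CA
  res_all <- unique(paste(atoms$resno[in_chain], atoms$insert[in_chain],
                          atoms$resid[in_chain]))
  res_ca <- unique(paste(atoms$resno[idx], atoms$insert[idx], atoms$resid[idx]))
  missing_ca <- setdiff(res_all, res_ca)
  missing_ca <- missing_ca[!grepl("HOH|CA$", missing_ca)]
  aa_like <- vapply(strsplit(missing_ca, " "), function(p) {
    nm <- p[length(p)]
    nchar(nm) == 3L && (nm %in% NONSTANDARD_RESIDUES || !grepl("[0-9]", nm))
  }, logical(1))
  if (any(aa_like))
    warning(sprintf("chain '%s': %d residue(s) without an alpha-carbon skipped",
                    chain_id, sum(aa_like)))

  n_models <- max(1L, nrow(as.matrix(pdb$xyz)))
  if (model < 1L || model > n_models)
    stop(sprintf("model %d not present (file has %d)", model, n_models))
  xyz <- as.matrix(pdb$xyz)[model, ]
  coords <- cbind(xyz[3L * idx - 2L], xyz[3L * idx - 1L], xyz[3L * idx])

  resno <- atoms$resno[idx]
  # authored numbering; remap if insertion codes break monotonicity
  ids <- as.integer(resno)
  if (length(ids) > 1L && any(diff(ids) <= 0L)) {
    mono <- ids
    for (i in 2:length(mono))
      if (mono[i] <= mono[i - 1L]) mono[i] <- mono[i - 1L] + 1L
    ids_use <- mono
  } else {
    ids_use <- ids
  }

  breaks <- empty_breaks()
  if (length(ids) > 1L) {
    gap <- which(diff(ids) > 1L)
    if (length(gap) > 0L)
      breaks <- data.frame(after_index = gap, kind = "numbering_gap",
                           span_residues = diff(ids)[gap] - 1L,
                           stringsAsFactors = FALSE)
  }

  new_chain(coords,
            residue_ids = ids_use,
            residue_names = atoms$resid[idx],
            chain_id = chain_id,
            model_index = as.integer(model),
            breaks = breaks,
            orig_residue_ids = ids)
}

#' Read a chain from a plain x-y-z coordinate file
#'
#' One vertex per non-empty line; the first three whitespace- or
#' comma-separated fields are taken as coordinates (extra columns are
#' ignored). Lines starting with `#` are comments. Residues are
#' numbered 1..N; no distance-based break scan is performed unless
#' requested afterwards via [detect_distance_breaks()].
#'
#' @param path path to the coordinate file.
#' @return a [new_chain()] object.
#' @export
read_xyz_chain <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L) stop(sprintf("no coordinates in %s", path))
  coords <- matrix(0, length(keep), 3L)
  for (i in seq_along(keep)) {
    ln <- gsub(",", " ", lines[keep[i]])
    fields <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(fields) < 3L)
      stop(sprintf("parse error at line %d of %s: fewer than 3 fields",
                   keep[i], path))
    vals <- suppressWarnings(as.numeric(fields[1:3]))
    if (anyNA(vals))
      stop(sprintf("parse error at line %d of %s: non-numeric field",
                   keep[i], path))
    coords[i, ] <- vals
  }
  new_chain(coords, chain_id = "X")
}

#' Write a chain in the simplified x-y-z format
#'
#' @param chain a `knot_chain`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_xyz <- function(chain, path) {
  m <- chain$vertices
  writeLines(sprintf("%.6f %.6f %.6f", m[, 1L], m[, 2L], m[, 3L]), path)
  invisible(path)
}

#' Flag suspiciously long virtual bonds as chain breaks
#'
#' The CA-CA virtual bond is close to 3.8 Angstrom in real chains;
#' adjacent vertices farther apart than `cutoff` indicate missing
#' structure that the file does not declare. Each such pair gains a
#' `distance_gap` break. The operation is idempotent and preserves
#' existing breaks.
#'
#' @param chain a `knot_chain`.
#' @param cutoff distance threshold in Angstrom (default 4.5, about
#'   1.15 times the canonical virtual bond).
#' @return the chain with updated breaks.
#' @export
detect_distance_breaks <- function(chain, cutoff = 4.5) {
  if (cutoff <= 0) stop("cutoff must be positive")
  n <- nrow(chain$vertices)
  if (n < 2L) return(chain)
  d <- sqrt(rowSums((chain$vertices[-1L, , drop = FALSE] -
                     chain$vertices[-n, , drop = FALSE])^2))
  hit <- which(d > cutoff)
  old <- chain$breaks
  hit <- setdiff(hit, old$after_index[old$kind == "distance_gap"])
  if (length(hit) > 0L) {
    add <- data.frame(after_index = hit, kind = "distance_gap",
                      span_residues = 0L, stringsAsFactors = FALSE)
    chain$breaks <- rbind(old, add)
    chain$breaks <- chain$breaks[order(chain$breaks$after_index), , drop = FALSE]
    rownames(chain$breaks) <- NULL
  }
  validate_chain(chain)
}

#' Bridge chain breaks with straight segments
#'
#' The geometry is unchanged (consecutive vertices are already joined
#' by straight segments); bridging marks every segment that spans a
#' break so that downstream results carry a machine-readable
#' "putative" flag, since a reconstructed segment can pierce the
#' existing chain and fake or destroy a knot.
#'
#' @param chain a `knot_chain`.
#' @return the chain with `bridged` flags set; see [is_putative()].
#' @export
bridge_breaks <- function(chain) {
  n <- nrow(chain$vertices)
  chain$bridged <- rep(FALSE, max(n - 1L, 0L))
  if (nrow(chain$breaks) > 0L)
    chain$bridged[chain$breaks$after_index] <- TRUE
  chain
}
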