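#' Read a structure into a coarse-grained C-alpha model
#'
#' Parses PDB-format coordinates and reduces them to one C-alpha atom per
#' residue, the representation used by the elastic network models in this
#' package.  Only the first MODEL of a multi-model file is used (the network
#' models take a single equilibrium structure).  For residues with alternate
#' locations the highest-occupancy C-alpha is kept (ties broken towards
#' altloc \code{"A"}, then file order).
#'
#' @param file Path to a PDB file, or a character string containing PDB text
#'   (recognised by the presence of a newline).
#' @param chains Optional character vector of chain identifiers to keep.
#' @param hetatm Either \code{"exclude"} (default: drop all HETATM records,
#'   including waters and ligands) or \code{"include"} (keep HETATM residues
#'   that have a C-alpha atom).
#' @param het_include Character vector of residue names (e.g. \code{"MSE"})
#'   to retain from HETATM records even under \code{hetatm = "exclude"}.
#'   Nonstandard residues recorded as ATOM are always retained: the network
#'   models are geometry-only.
#' @return An object of class \code{"calpha_model"}: a list with
#'   \code{residues} (data frame with columns \code{chain}, \code{resno},
#'   \code{insert}, \code{resid}, in file order), \code{xyz} (N x 3 matrix of
#'   coordinates in Angstrom) and \code{source} (input identifier).
#' @examples
#' pdb <- make_two_domain(n1 = 8, n2 = 8, seed = 1)
#' f <- tempfile(fileext = ".pdb")
#' write_labeled_pdb(pdb$model, rep(1L, n_residues(pdb$model)), file = f)
#' m <- read_calpha(f)
#' n_residues(m)
#' @export
read_calpha <- function(file, chains = NULL,
                        hetatm = c("exclude", "include"),
                        het_include = character()) {
  hetatm <- match.arg(hetatm)
  src <- "pdb_text"
  if (length(file) == 1 && !grepl("\n", file)) {
    if (!file.exists(file)) stop("file not found: ", file)
    src <- basename(file)
    path <- file
  } else {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(unlist(strsplit(paste(file, collapse = "\n"), "\n")), path)
  }

  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("cannot parse PDB input (", conditionMessage(e),
                             ")", call. = FALSE))
  atoms <- pdb$atom

  keep <- atoms$elety == "CA" &
    (atoms$type == "ATOM" |
       (atoms$type == "HETATM" &
          (hetatm == "include" | atoms$resid %in% het_include)))
  # calcium ions also carry atom name CA; require a carbon element when the
  # element column is informative
  elesy <- trimws(atoms$elesy)
  keep <- keep & (is.na(elesy) | elesy == "" | elesy == "C")
  atoms <- atoms[keep, , drop = FALSE]

  if (!is.null(chains)) atoms <- atoms[atoms$chain %in% chains, , drop = FALSE]
  if (nrow(atoms) == 0) stop("empty selection: no C-alpha atoms after filtering",
                             call. = FALSE)

  ins <- atoms$insert
  ins[is.na(ins)] <- ""
  key <- paste(atoms$chain, atoms$resno, ins, sep = "\r")

  # altloc policy: highest occupancy, ties -> altloc 'A', then first occurrence
  occ <- atoms$o
  occ[is.na(occ)] <- 1
  alt <- atoms$alt
  alt[is.na(alt)] <- ""
  ord <- order(match(key, unique(key)), -occ, alt != "A" & alt != "", seq_len(nrow(atoms)))
  atoms <- atoms[ord, , drop = FALSE]
  ins <- ins[ord]
  key <- key[ord]
  first <- !duplicated(key)
  atoms <- atoms[first, , drop = FALSE]
  ins <- ins[first]

  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  if (any(!is.finite(xyz))) {
    bad <- which(rowSums(!is.finite(xyz)) > 0)[1]
    stop("malformed coordinate fields for residue ", atoms$chain[bad], " ",
         atoms$resno[bad], call. = FALSE)
  }
  dimnames(xyz) <- NULL

  new_calpha_model(
    residues = data.frame(chain = atoms$chain, resno = atoms$resno,
                          insert = ins, resid = atoms$resid,
                          stringsAsFactors = FALSE),
    xyz = xyz, source = src)
}

new_calpha_model <- function(residues, xyz, source = "model") {
  stopifnot(nrow(residues) == nrow(xyz), ncol(xyz) == 3)
  structure(list(residues = residues, xyz = xyz, source = source),
            class = "calpha_model")
}

#' Number of residues in a C-alpha model
#' @param model A \code{"calpha_model"}.
#' @return Integer residue count.
#' @export
n_residues <- function(model) {
  stopifnot(inherits(model, "calpha_model"))
  nrow(model$residues)
}

#' @export
print.calpha_model <- function(x, ...) {
  ch <- unique(x$residues$chain)
  cat("C-alpha model '", x$source, "': ", n_residues(x), " residues, ",
      length(ch), " chain(s) [", paste(ch, collapse = " "), "]\n", sep = "")
  invisible(x)
}

flatten_xyz <- function(xyz) as.vector(t(xyz))

write_pdb_lines <- function(model, xyz_frames, b = NULL) {
  f <- tempfile(fileext = ".pdb")
  on.exit(unlink(f), add = TRUE)
  res <- model$residues
  ins <- res$insert
  ins[ins == ""] <- NA
  bio3d::write.pdb(file = f, xyz = xyz_frames,
                   resno = res$resno, chain = res$chain, insert = ins,
                   resid = res$resid, elety = rep("CA", nrow(res)),
                   b = if (is.null(b)) rep(0, nrow(res)) else b)
  readLines(f)
}

#' Write a community-labeled PDB
#'
#' Emits PDB text in which the B-factor column of every atom of residue i
#' carries the (1-based) community index of residue i, so that structures can
#' be coloured by community in any molecular viewer.  When the original
#' all-atom PDB text is supplied, its full atom records are re-emitted with
#' relabeled B-factors (atoms of residues outside the model keep B = 0.00);
#' otherwise C-alpha-only records are written from the model.
#'
#' @param model A \code{"calpha_model"}.
#' @param labels Integer vector of per-residue community indices, length N.
#' @param file Output path, or \code{NULL} to return the lines invisibly only.
#' @param original Optional path to (or text of) the original PDB whose atom
#'   records should be relabeled.
#' @return Invisibly, the character vector of PDB lines.
#' @export
write_labeled_pdb <- function(model, labels, file = NULL, original = NULL) {
  stopifnot(inherits(model, "calpha_model"))
  if (length(labels) != n_residues(model))
    stop("labels length (", length(labels), ") does not match model size (",
         n_residues(model), ")", call. = FALSE)
  labels <- as.numeric(labels)

  if (is.null(original)) {
    lines <- write_pdb_lines(model, matrix(flatten_xyz(model$xyz), nrow = 1),
                             b = labels)
  } else {
    path <- original
    if (grepl("\n", original[1]) || length(original) > 1) {
      path <- tempfile(fileext = ".pdb")
      on.exit(unlink(path), add = TRUE)
      writeLines(unlist(strsplit(paste(original, collapse = "\n"), "\n")), path)
    }
    pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE,
                                            rm.alt = FALSE, verbose = FALSE))
    ins <- pdb$atom$insert
    ins[is.na(ins)] <- ""
    akey <- paste(pdb$atom$chain, pdb$atom$resno, ins, sep = "\r")
    mkey <- paste(model$residues$chain, model$residues$resno,
                  model$residues$insert, sep = "\r")
    b <- labels[match(akey, mkey)]
    b[is.na(b)] <- 0
    f <- tempfile(fileext = ".pdb")
    on.exit(unlink(f), add = TRUE)
    pdb$atom$b <- b
    bio3d::write.pdb(pdb, file = f)
    lines <- readLines(f)
  }
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Write a multi-model C-alpha trajectory PDB
#'
#' Writes a list of coordinate frames as a multi-model PDB (one MODEL/ENDMDL
#' block per frame, C-alpha records only), the format used to animate normal
#' mode motions.
#'
#' @param frames List of N x 3 coordinate matrices, or a
#'   \code{"motion_trajectory"} object from \code{\link{anm_trajectory}}.
#' @param model A \code{"calpha_model"} supplying residue identities.
#' @param file Output path, or \code{NULL}.
#' @return Invisibly, the character vector of PDB lines.
#' @export
write_trajectory_pdb <- function(frames, model, file = NULL) {
  stopifnot(inherits(model, "calpha_model"))
  if (inherits(frames, "motion_trajectory")) frames <- frames$frames
  if (!is.list(frames) || length(frames) == 0)
    stop("frames must be a non-empty list of N x 3 matrices", call. = FALSE)
  n <- n_residues(model)
  ok <- vapply(frames, function(f) is.matrix(f) && all(dim(f) == c(n, 3)),
               logical(1))
  if (!all(ok)) stop("frame shape mismatch: expected ", n, " x 3", call. = FALSE)
  xyz <- do.call(rbind, lapply(frames, flatten_xyz))
  lines <- write_pdb_lines(model, xyz)
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Write a community assignment table
#'
#' @param model A \code{"calpha_model"}.
#' @param labels Per-residue community indices (1-based), length N.
#' @param file Output path for a TSV with columns \code{chain}, \code{resnum},
#'   \code{icode}, \code{community}.
#' @return Invisibly, the data frame written.
#' @export
write_assignments <- function(model, labels, file) {
  stopifnot(inherits(model, "calpha_model"),
            length(labels) == n_residues(model))
  df <- data.frame(chain = model$residues$chain,
                   resnum = model$residues$resno,
                   icode = model$residues$insert,
                   community = as.integer(labels),
                   stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Optimal-superposition C-alpha RMSD between two models
#'
#' Least-squares (Kabsch) superposition of two equal-length C-alpha models,
#' returning the root-mean-square deviation in Angstrom.  Used e.g. to
#' quantify the structural difference between two conformational states
#' whose community decompositions are being compared.
#'
#' @param a,b \code{"calpha_model"} objects or N x 3 coordinate matrices with
#'   residues in 1:1 correspondence.
#' @return RMSD in Angstrom (single number).
#' @export
superposed_rmsd <- function(a, b) {
  xa <- if (inherits(a, "calpha_model")) a$xyz else a
  xb <- if (inherits(b, "calpha_model")) b$xyz else b
  stopifnot(is.matrix(xa), is.matrix(xb), ncol(xa) == 3, ncol(xb) == 3)
  if (nrow(xa) != nrow(xb))
    stop("models have different residue counts (", nrow(xa), " vs ",
         nrow(xb), "); supply matched selections", call. = FALSE)
  va <- flatten_xyz(xa)
  vb <- flatten_xyz(xb)
  fitted <- suppressWarnings(
    bio3d::fit.xyz(fixed = va, mobile = matrix(vb, nrow = 1)))
  bio3d::rmsd(va, fitted)
}
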