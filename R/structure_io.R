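#' @useDynLib cvstates, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Atom selection mini-language
#
# Grammar (case-insensitive keywords, whitespace-separated tokens):
#   expr      := term ("or" term)*
#   term      := factor ("and" factor)*
#   factor    := "not" factor | "(" expr ")" | primitive
#   primitive := "all"
#              | "chain" <id>+
#              | "name"  <id>+
#              | "resid" <n | a:b>+
# ---------------------------------------------------------------------------

.sel_tokenize <- function(expression) {
  x <- gsub("([()])", " \\1 ", expression)
  toks <- strsplit(trimws(x), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

.sel_keywords <- c("and", "or", "not", "all", "chain", "name", "resid", "(", ")")

# Recursive-descent parser; returns a function(atoms) -> logical vector.
.sel_parse <- function(toks) {
  pos <- 1L
  peek <- function() if (pos <= length(toks)) tolower(toks[pos]) else NA_character_
  advance <- function() {
    t <- toks[pos]
    pos <<- pos + 1L
    t
  }

  parse_primitive <- function() {
    if (is.na(peek())) {
      stop("selection syntax error: unexpected end of expression", call. = FALSE)
    }
    kw <- tolower(advance())
    if (kw == "all") {
      return(function(atoms) rep(TRUE, nrow(atoms)))
    }
    if (!kw %in% c("chain", "name", "resid")) {
      stop("selection syntax error: unexpected token '", kw, "'", call. = FALSE)
    }
    args <- character(0)
    while (!is.na(peek()) && !peek() %in% .sel_keywords) args <- c(args, advance())
    if (length(args) == 0L) {
      stop("selection syntax error: '", kw, "' needs at least one argument",
           call. = FALSE)
    }
    if (kw == "chain") {
      return(function(atoms) atoms$chain %in% args)
    }
    if (kw == "name") {
      return(function(atoms) atoms$name %in% args)
    }
    # resid: integers or inclusive ranges a:b
    keep <- integer(0)
    for (a in args) {
      if (grepl("^-?[0-9]+:-?[0-9]+$", a)) {
        ab <- as.integer(strsplit(a, ":")[[1]])
        keep <- c(keep, seq(ab[1], ab[2]))
      } else if (grepl("^-?[0-9]+$", a)) {
        keep <- c(keep, as.integer(a))
      } else {
        stop("selection syntax error: bad resid token '", a, "'", call. = FALSE)
      }
    }
    function(atoms) atoms$resid %in% keep
  }

  parse_factor <- function() {
    if (identical(peek(), "not")) {
      advance()
      f <- parse_factor()
      return(function(atoms) !f(atoms))
    }
    if (identical(peek(), "(")) {
      advance()
      f <- parse_expr()
      if (!identical(peek(), ")")) stop("selection syntax error: missing ')'", call. = FALSE)
      advance()
      return(f)
    }
    parse_primitive()
  }

  parse_term <- function() {
    f <- parse_factor()
    while (identical(peek(), "and")) {
      advance()
      g <- parse_factor()
      f <- local({
        a <- f; b <- g
        function(atoms) a(atoms) & b(atoms)
      })
    }
    f
  }

  parse_expr <- function() {
    f <- parse_term()
    while (identical(peek(), "or")) {
      advance()
      g <- parse_term()
      f <- local({
        a <- f; b <- g
        function(atoms) a(atoms) | b(atoms)
      })
    }
    f
  }

  out <- parse_expr()
  if (pos <= length(toks)) {
    stop("selection syntax error: trailing tokens from '", toks[pos], "'", call. = FALSE)
  }
  out
}

#' Resolve an atom selection expression against an atom table
#'
#' Selections use a small language with primitives `all`, `chain <id>...`,
#' `name <atom name>...` and `resid <n|a:b>...`, combined with `and`, `or`,
#' `not` and parentheses, e.g. `"chain A and name CA"` or
#' `"resid 1:50 60 and not name CB"`.
#'
#' @param atoms data.frame with columns `chain`, `resid`, `name` (schema order)
#' @param expression selection string
#' @return integer vector of atom indices in schema order
#' @export
select_atoms <- function(atoms, expression = "all") {
  stopifnot(is.data.frame(atoms))
  f <- .sel_parse(.sel_tokenize(expression))
  idx <- which(f(atoms))
  idx
}

# ---------------------------------------------------------------------------
# Structure ensembles
# ---------------------------------------------------------------------------

.atom_key <- function(atoms) paste(atoms$chain, atoms$resid, atoms$name, sep = "|")

.read_pdb_structures <- function(path) {
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
    error = function(e) stop("cannot read PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  sel <- which(pdb$atom$type == "ATOM")
  if (length(sel) == 0L) stop("no ATOM records in '", path, "'", call. = FALSE)
  at <- pdb$atom[sel, , drop = FALSE]
  ins <- at$insert
  if (any(!is.na(ins) & nzchar(trimws(ins)))) {
    stop("PDB file '", path, "' contains insertion codes, which are not supported ",
         "(AlphaFold2 output never carries them); renumber the residues first",
         call. = FALSE)
  }
  atoms <- data.frame(
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resid = as.integer(at$resno),
    resname = at$resid,
    name = at$elety,
    b = as.numeric(at$b),
    stringsAsFactors = FALSE
  )
  # drop alternate-location duplicates: keep first occurrence of each key
  keep <- !duplicated(.atom_key(atoms))
  atoms <- atoms[keep, , drop = FALSE]
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_models <- nrow(xyz)
  structures <- vector("list", n_models)
  col_idx <- rep((which(pdb$atom$type == "ATOM")[keep] - 1L) * 3L, each = 3L) +
    rep(1:3, sum(keep))
  for (m in seq_len(n_models)) {
    coords <- matrix(xyz[m, col_idx], ncol = 3, byrow = TRUE)
    if (!all(is.finite(coords))) {
      stop("non-finite coordinates in '", path, "' model ", m, call. = FALSE)
    }
    structures[[m]] <- coords
  }
  ids <- if (n_models > 1L) paste0(basename(path), "#", seq_len(n_models)) else basename(path)
  list(atoms = atoms, xyz = structures, ids = ids, path = path)
}

#' Load an ensemble of PDB structures
#'
#' Reads a set of single-model PDB files (or multi-model files, expanded one
#' structure per MODEL record), harmonizes the atom schema across structures
#' by intersecting `(chain, resid, atom name)` keys, and applies an atom
#' selection. Per-structure confidence is taken as the mean of the B-factor
#' column over the selected atoms; for AlphaFold2 output this is the mean
#' pLDDT.
#'
#' Structures on which the selection resolves to zero atoms are dropped with
#' a warning. An empty harmonized schema is an error.
#'
#' @param paths character vector of PDB paths; entries containing `*` or `?`
#'   are expanded as globs
#' @param selection atom selection expression (see [select_atoms()])
#' @return a `StructureEnsemble`: list with `xyz` (list of n_atoms x 3
#'   matrices, Angstrom), `atoms` (schema table), `source_ids`, `mean_plddt`
#' @export
load_ensemble <- function(paths, selection = "all") {
  expanded <- unlist(lapply(paths, function(p) {
    if (grepl("[*?]", p)) sort(Sys.glob(p)) else p
  }), use.names = FALSE)
  if (length(expanded) == 0L) stop("no input structure files", call. = FALSE)
  missing <- expanded[!file.exists(expanded)]
  if (length(missing)) {
    stop("structure file not found: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  raw <- lapply(expanded, .read_pdb_structures)

  atoms_list <- list()
  xyz_list <- list()
  ids <- character(0)
  for (r in raw) {
    for (m in seq_along(r$xyz)) {
      atoms_list[[length(atoms_list) + 1L]] <- r$atoms
      xyz_list[[length(xyz_list) + 1L]] <- r$xyz[[m]]
      ids <- c(ids, r$ids[m])
    }
  }

  # drop structures on which the selection resolves to nothing
  keep <- vapply(atoms_list, function(a) length(select_atoms(a, selection)) > 0L,
                 logical(1))
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " structure(s) with no atoms matching ",
            "selection '", selection, "': ",
            paste(ids[!keep], collapse = ", "), call. = FALSE)
  }
  if (!any(keep)) {
    stop("selection '", selection, "' matches no atoms in any structure", call. = FALSE)
  }
  atoms_list <- atoms_list[keep]
  xyz_list <- xyz_list[keep]
  ids <- ids[keep]

  keys <- lapply(atoms_list, .atom_key)
  shared <- Reduce(intersect, keys)
  if (length(shared) == 0L) {
    stop("atom schema intersection across structures is empty; the files do ",
         "not describe the same molecule", call. = FALSE)
  }
  # schema ordered as in the first retained structure
  schema_keys <- keys[[1]][keys[[1]] %in% shared]
  schema <- atoms_list[[1]][match(schema_keys, keys[[1]]), , drop = FALSE]
  sel_idx <- select_atoms(schema, selection)
  if (length(sel_idx) == 0L) {
    stop("selection '", selection, "' matches no atoms in the harmonized schema",
         call. = FALSE)
  }
  schema <- schema[sel_idx, , drop = FALSE]
  schema_keys <- schema_keys[sel_idx]
  rownames(schema) <- NULL

  n <- length(xyz_list)
  out_xyz <- vector("list", n)
  mean_plddt <- numeric(n)
  for (i in seq_len(n)) {
    m <- match(schema_keys, keys[[i]])
    out_xyz[[i]] <- xyz_list[[i]][m, , drop = FALSE]
    mean_plddt[i] <- mean(atoms_list[[i]]$b[m])
  }
  # B-factors are per-structure: refresh the schema table's b column lazily
  schema$b <- atoms_list[[1]]$b[match(schema_keys, keys[[1]])]

  structure(
    list(xyz = out_xyz, atoms = schema, source_ids = ids, mean_plddt = mean_plddt),
    class = "StructureEnsemble"
  )
}

#' @export
print.StructureEnsemble <- function(x, ...) {
  cat("StructureEnsemble:", length(x$xyz), "structures,",
      nrow(x$atoms), "atoms each\n")
  cat("  mean pLDDT range:", sprintf("%.1f-%.1f", min(x$mean_plddt), max(x$mean_plddt)), "\n")
  invisible(x)
}

#' Number of structures in an ensemble
#' @param ensemble a `StructureEnsemble`
#' @export
n_structures <- function(ensemble) length(ensemble$xyz)

.subset_ensemble <- function(ensemble, idx) {
  structure(
    list(xyz = ensemble$xyz[idx], atoms = ensemble$atoms,
         source_ids = ensemble$source_ids[idx],
         mean_plddt = ensemble$mean_plddt[idx]),
    class = "StructureEnsemble"
  )
}

# ---------------------------------------------------------------------------
# Rigid superposition (Kabsch) and RMSD
# ---------------------------------------------------------------------------

.rmsd_xyz <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Optimal rigid-body superposition of two coordinate sets
#'
#' Least-squares superposition of `mobile` onto `reference` (Kabsch via SVD,
#' proper rotation only — reflections are excluded). The fit is computed on
#' `fit_selection`; the whole mobile structure is transformed. RMSD is
#' reported over `rmsd_selection` (defaults to the fit selection).
#'
#' @param mobile,reference n x 3 coordinate matrices (Angstrom)
#' @param fit_selection integer atom indices used for the fit (default: all)
#' @param rmsd_selection indices over which the RMSD is reported
#' @return list with `xyz` (transformed mobile coordinates), `rmsd` (Angstrom),
#'   `rotation` (3 x 3), `translation` (length 3)
#' @export
superpose <- function(mobile, reference, fit_selection = NULL,
                      rmsd_selection = fit_selection) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (is.null(fit_selection)) fit_selection <- seq_len(nrow(mobile))
  if (is.null(rmsd_selection)) rmsd_selection <- fit_selection
  if (!identical(ncol(mobile), 3L) || !identical(ncol(reference), 3L)) {
    stop("coordinates must be n x 3 matrices", call. = FALSE)
  }
  if (nrow(mobile) != nrow(reference)) {
    stop("mobile and reference atom counts differ", call. = FALSE)
  }
  if (length(fit_selection) < 3L) {
    stop("superposition needs at least 3 fit atoms", call. = FALSE)
  }
  P <- mobile[fit_selection, , drop = FALSE]
  Q <- reference[fit_selection, , drop = FALSE]
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  # degenerate (collinear) fit sets have rank < 2
  sv <- svd(Qc)$d
  if (sv[2] < 1e-8 * max(sv[1], 1)) {
    stop("fit atoms are collinear; superposition is under-determined", call. = FALSE)
  }
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  transformed <- sweep(mobile, 2, cp) %*% t(R)
  transformed <- sweep(transformed, 2, cq, "+")
  list(
    xyz = transformed,
    rmsd = .rmsd_xyz(transformed[rmsd_selection, , drop = FALSE],
                     reference[rmsd_selection, , drop = FALSE]),
    rotation = R,
    translation = as.numeric(cq - cp %*% t(R))
  )
}

# ---------------------------------------------------------------------------
# CV time series
# ---------------------------------------------------------------------------

#' Construct a multivariate CV time-series container
#'
#' @param trajectories list of numeric matrices (frames x CVs) sharing one
#'   column schema; a single matrix is wrapped in a list
#' @param dt time between frames (unit-agnostic metadata)
#' @param column_names CV names; defaults to matrix colnames or cv1, cv2, ...
#' @param traj_ids per-trajectory identifiers
#' @return a `TimeSeries` object
#' @export
timeseries <- function(trajectories, dt = 1, column_names = NULL, traj_ids = NULL) {
  if (is.matrix(trajectories) || is.data.frame(trajectories)) {
    trajectories <- list(as.matrix(trajectories))
  }
  trajectories <- lapply(trajectories, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  if (length(trajectories) == 0L) stop("no trajectories", call. = FALSE)
  ncols <- vapply(trajectories, ncol, integer(1))
  if (length(unique(ncols)) != 1L) {
    stop("trajectories disagree on CV count: ", paste(ncols, collapse = ", "),
         call. = FALSE)
  }
  if (any(vapply(trajectories, nrow, integer(1)) < 2L)) {
    stop("each trajectory needs at least 2 frames", call. = FALSE)
  }
  if (any(!vapply(trajectories, function(m) all(is.finite(m)), logical(1)))) {
    stop("trajectories contain missing or non-finite values", call. = FALSE)
  }
  if (is.null(column_names)) column_names <- colnames(trajectories[[1]])
  if (is.null(column_names)) column_names <- paste0("cv", seq_len(ncols[1]))
  if (length(column_names) != ncols[1]) {
    stop("column_names length does not match CV count", call. = FALSE)
  }
  trajectories <- lapply(trajectories, function(m) {
    colnames(m) <- column_names
    m
  })
  if (is.null(traj_ids)) traj_ids <- paste0("traj", seq_along(trajectories))
  structure(
    list(trajectories = trajectories, dt = dt,
         column_names = column_names, traj_ids = traj_ids),
    class = "TimeSeries"
  )
}

#' @export
print.TimeSeries <- function(x, ...) {
  nf <- vapply(x$trajectories, nrow, integer(1))
  cat("TimeSeries:", length(x$trajectories), "trajectories,",
      length(x$column_names), "CVs,", sum(nf), "frames total (dt =", x$dt, ")\n")
  invisible(x)
}

#' Pool all frames of a time series into one matrix
#' @param ts a `TimeSeries`
#' @return frames x CVs matrix (trajectories stacked in order)
#' @export
ts_pool <- function(ts) do.call(rbind, ts$trajectories)

.read_ts_file <- function(path) {
  if (!file.exists(path)) stop("time-series file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty time-series file: ", path, call. = FALSE)
  header <- NULL
  if (startsWith(trimws(lines[1]), "#")) {
    h <- sub("^[[:space:]]*#[[:space:]]*", "", lines[1])
    header <- strsplit(h, "[,[:space:]]+")[[1]]
    header <- header[nzchar(header)]
    lines <- lines[-1]
  }
  sep <- if (grepl(",", lines[1])) "," else ""
  df <- utils::read.table(text = lines, sep = sep, header = FALSE,
                          colClasses = "numeric", comment.char = "#")
  m <- as.matrix(df)
  if (!is.numeric(m) || !all(is.finite(m))) {
    stop("non-numeric or missing entries in time-series file: ", path, call. = FALSE)
  }
  if (!is.null(header)) {
    if (length(header) != ncol(m)) {
      stop("header names ", length(header), " columns but data has ", ncol(m),
           " in: ", path, call. = FALSE)
    }
    colnames(m) <- header
  }
  m
}

#' Load CV time series from tabular text files
#'
#' Each file becomes one trajectory (trajectories are never concatenated
#' across the time axis). Files are whitespace- or comma-delimited, one row
#' per frame, one column per CV, with an optional leading `# name1 name2 ...`
#' header line naming the columns.
#'
#' @param files character vector of paths
#' @param dt time between frames (metadata)
#' @param column_names optional CV names overriding any file header
#' @return a `TimeSeries`
#' @export
load_timeseries <- function(files, dt = 1, column_names = NULL) {
  mats <- lapply(files, .read_ts_file)
  if (is.null(column_names)) column_names <- colnames(mats[[1]])
  timeseries(mats, dt = dt, column_names = column_names,
             traj_ids = basename(files))
}

#' Write a time series to tabular text files
#'
#' One whitespace-delimited file per trajectory with a `#`-prefixed header
#' naming the CVs; the inverse of [load_timeseries()].
#'
#' @param ts a `TimeSeries`
#' @param files output paths, one per trajectory
#' @param digits significant digits written
#' @return `files`, invisibly
#' @export
write_timeseries <- function(ts, files, digits = 10) {
  stopifnot(inherits(ts, "TimeSeries"))
  if (length(files) != length(ts$trajectories)) {
    stop("need one output file per trajectory", call. = FALSE)
  }
  for (i in seq_along(files)) {
    con <- file(files[i], "w")
    writeLines(paste("#", paste(ts$column_names, collapse = " ")), con)
    utils::write.table(format(ts$trajectories[[i]], digits = digits, trim = TRUE,
                              scientific = FALSE),
                       con, row.names = FALSE, col.names = FALSE, quote = FALSE)
    close(con)
  }
  invisible(files)
}
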