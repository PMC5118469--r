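ARCHIVE_VERSION <- "1"

#' Save a fitted CCA model (and optional results) to HDF5
#'
#' Layout: group `/meta` carries scalar attributes (`version`, `reg`,
#' `numCC`, `ktype`, `gausigma`, `degree`, `cutoff`); `/cancorrs` and
#' per-dataset groups `/dataset<i>/weights|comps|means` hold the model
#' arrays. Optional payloads are written under `/validation/<i>/preds|corrs`
#' ([predict_heldout()] result), `/ev/<i>` ([explained_variance()] result)
#' and `/cv` (score grid plus `best_reg` / `best_numCC` from
#' [grid_search()]). Arrays round-trip bit for bit.
#'
#' @param model A fitted `cca_model`.
#' @param path Destination file path (overwritten if present).
#' @param validation Optional `prediction_result` to store.
#' @param ev Optional `ev_result` to store.
#' @param cv Optional `cv_result` to store.
#' @param cutoff Pseudoinverse cutoff to record in the metadata (default 0).
#' @return `path`, invisibly.
#' @seealso [load_model()]
#' @export
save_model <- function(model, path, validation = NULL, ev = NULL, cv = NULL,
                       cutoff = 0) {
  stopifnot(inherits(model, "cca_model"))
  if (file.exists(path)) file.remove(path)
  ok <- tryCatch(rhdf5::h5createFile(path), error = function(e) FALSE)
  if (!isTRUE(ok))
    stop("cannot write model archive at '", path, "'", call. = FALSE)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  h5 <- function(obj, name) rhdf5::h5write(obj, path, name)

  rhdf5::h5createGroup(path, "meta")
  fid <- rhdf5::H5Fopen(path)
  gid <- rhdf5::H5Gopen(fid, "meta")
  rhdf5::h5writeAttribute(ARCHIVE_VERSION, gid, "version")
  rhdf5::h5writeAttribute(model$reg, gid, "reg")
  rhdf5::h5writeAttribute(model$n_components, gid, "numCC")
  rhdf5::h5writeAttribute(model$kernel$ktype %||% "none", gid, "ktype")
  rhdf5::h5writeAttribute(model$kernel$gausigma %||% 1.0, gid, "gausigma")
  rhdf5::h5writeAttribute(model$kernel$degree %||% 2L, gid, "degree")
  rhdf5::h5writeAttribute(cutoff, gid, "cutoff")
  rhdf5::H5Gclose(gid)
  rhdf5::H5Fclose(fid)

  h5(model$cancorrs, "cancorrs")
  h5(model$eigenvalues, "eigenvalues")
  for (i in seq_along(model$weights)) {
    g <- paste0("dataset", i)
    rhdf5::h5createGroup(path, g)
    h5(model$weights[[i]], paste0(g, "/weights"))
    h5(model$components[[i]], paste0(g, "/comps"))
    h5(model$training_means[[i]], paste0(g, "/means"))
  }
  if (!is.null(validation)) {
    rhdf5::h5createGroup(path, "validation")
    for (i in seq_along(validation$preds)) {
      g <- paste0("validation/", i)
      rhdf5::h5createGroup(path, g)
      h5(validation$preds[[i]], paste0(g, "/preds"))
      h5(validation$corrs[[i]], paste0(g, "/corrs"))
    }
  }
  if (!is.null(ev)) {
    rhdf5::h5createGroup(path, "ev")
    for (i in seq_along(ev$ev)) h5(ev$ev[[i]], paste0("ev/", i))
  }
  if (!is.null(cv)) {
    rhdf5::h5createGroup(path, "cv")
    h5(unclass(cv$score_grid), "cv/score_grid")
    h5(cv$regs, "cv/regs")
    h5(cv$numCCs, "cv/numCCs")
    fid <- rhdf5::H5Fopen(path)
    gid <- rhdf5::H5Gopen(fid, "cv")
    rhdf5::h5writeAttribute(cv$best_reg, gid, "best_reg")
    rhdf5::h5writeAttribute(cv$best_numCC, gid, "best_numCC")
    rhdf5::H5Gclose(gid)
    rhdf5::H5Fclose(fid)
  }
  invisible(path)
}

#' Load a CCA model archive from HDF5
#'
#' Restores a `cca_model` saved by [save_model()], immediately usable with
#' [predict_heldout()] and [explained_variance()]. Optional payloads, when
#' present in the file, are attached as attributes `validation`, `ev` and
#' `cv` of the returned model. A file whose format-version tag differs from
#' the version this package writes is refused.
#'
#' @param path Path of an archive written by [save_model()].
#' @return A `cca_model`.
#' @export
load_model <- function(path) {
  if (!file.exists(path))
    stop("model archive not found: '", path, "'", call. = FALSE)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  listing <- tryCatch(rhdf5::h5ls(path),
                      error = function(e)
                        stop("corrupt model archive '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  entries <- ifelse(listing$group == "/",
                    paste0("/", listing$name),
                    paste0(listing$group, "/", listing$name))
  for (grp in c("/meta", "/cancorrs", "/dataset1/weights")) {
    if (!grp %in% entries)
      stop("corrupt model archive: missing group '", grp, "'",
           call. = FALSE)
  }
  meta <- rhdf5::h5readAttributes(path, "meta")
  if (is.null(meta$version) || !identical(as.character(meta$version),
                                          ARCHIVE_VERSION))
    stop("unsupported archive version '",
         as.character(meta$version %||% "<missing>"),
         "' (this package reads version ", ARCHIVE_VERSION, ")",
         call. = FALSE)
  nds <- sum(grepl("^dataset[0-9]+$", listing$name) & listing$group == "/")
  rd <- function(name) rhdf5::h5read(path, name)
  kernel <- if (identical(as.character(meta$ktype), "none")) NULL else
    kernel_spec(as.character(meta$ktype), gausigma = as.numeric(meta$gausigma),
                degree = as.integer(meta$degree))
  model <- structure(
    list(reg = as.numeric(meta$reg),
         n_components = as.integer(meta$numCC),
         kernel = kernel,
         weights = lapply(seq_len(nds), function(i)
           rd(paste0("dataset", i, "/weights"))),
         components = lapply(seq_len(nds), function(i)
           rd(paste0("dataset", i, "/comps"))),
         cancorrs = as.numeric(rd("cancorrs")),
         training_means = lapply(seq_len(nds), function(i)
           as.numeric(rd(paste0("dataset", i, "/means")))),
         eigenvalues = as.numeric(rd("eigenvalues"))),
    class = "cca_model"
  )
  if (any(listing$group == "/" & listing$name == "validation")) {
    ii <- sort(as.integer(listing$name[listing$group == "/validation"]))
    attr(model, "validation") <- structure(
      list(preds = lapply(ii, function(i) rd(paste0("validation/", i, "/preds"))),
           corrs = lapply(ii, function(i)
             as.numeric(rd(paste0("validation/", i, "/corrs"))))),
      class = "prediction_result")
  }
  if (any(listing$group == "/" & listing$name == "ev")) {
    ii <- sort(as.integer(listing$name[listing$group == "/ev"]))
    attr(model, "ev") <- structure(
      list(ev = lapply(ii, function(i) rd(paste0("ev/", i)))),
      class = "ev_result")
  }
  if (any(listing$group == "/" & listing$name == "cv")) {
    cvattr <- rhdf5::h5readAttributes(path, "cv")
    attr(model, "cv") <- list(
      score_grid = rd("cv/score_grid"),
      regs = as.numeric(rd("cv/regs")),
      numCCs = as.integer(rd("cv/numCCs")),
      best_reg = as.numeric(cvattr$best_reg),
      best_numCC = as.integer(cvattr$best_numCC))
  }
  model
}

#' Read datasets from delimited text or HDF5 files
#'
#' Text files are whitespace-delimited, one sample per row, with no header;
#' lines starting with `#` are comments. HDF5 files (extensions `.h5`,
#' `.hdf5`, `.hdf`) must contain a single 2-D dataset. All files must agree
#' on the number of rows.
#'
#' @param paths Character vector of file paths.
#' @return List of `data_block`s, one per file (centered, with column
#'   means recorded).
#' @export
read_datasets <- function(paths) {
  blocks <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("file not found: '", p, "'", call. = FALSE)
    if (grepl("\\.(h5|hdf5|hdf)$", p, ignore.case = TRUE))
      data_block(read_h5_matrix(p))
    else
      data_block(read_text_matrix(p))
  })
  ns <- vapply(blocks, function(b) nrow(b$values), integer(1))
  if (length(unique(ns)) != 1)
    stop("sample-count mismatch: ",
         paste(sprintf("%s (%d rows)", paths, ns), collapse = ", "),
         call. = FALSE)
  blocks
}

read_h5_matrix <- function(path) {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls <- rhdf5::h5ls(path)
  ds <- ls[ls$otype == "H5I_DATASET" & lengths(strsplit(ls$dim, " x ")) == 2, ]
  if (nrow(ds) == 0)
    stop("no 2-D dataset found in '", path, "'", call. = FALSE)
  nm <- paste0(sub("/$", "", ds$group[1]), "/", ds$name[1])
  as.matrix(rhdf5::h5read(path, nm))
}

read_text_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(keep)) stop("no data rows in '", path, "'", call. = FALSE)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  nf <- lengths(fields)
  if (length(unique(nf)) != 1) {
    i <- which(nf != nf[1])[1]
    stop("ragged row in '", path, "' at line ", keep[i], ": expected ",
         nf[1], " fields, found ", nf[i], call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(unlist(fields)))
  if (anyNA(vals)) {
    bad <- keep[ceiling(which(is.na(vals))[1] / nf[1])]
    stop("non-numeric value in '", path, "' at line ", bad, call. = FALSE)
  }
  matrix(vals, nrow = length(keep), ncol = nf[1], byrow = TRUE)
}

#' Write a matrix as whitespace-delimited text
#'
#' Companion to [read_datasets()]: full-precision, one sample per row, no
#' header.
#'
#' @param x Numeric matrix.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(x, path) {
  x <- as.matrix(x)
  lines <- apply(x, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}
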