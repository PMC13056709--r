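# Readers and writers for the standard formats the pipeline touches:
# 10x-style Matrix-Market triplets for counts, GMT for gene sets, CSV for
# per-cell tables. Gene identity is the features-file first column (ids);
# symbols are annotation only — all joins are on id.

#' Read a 10x-style Matrix-Market count directory
#'
#' Expects `matrix.mtx`, `features.tsv` (at least id and symbol columns) and
#' `barcodes.tsv`, optionally gzipped. The matrix is returned in
#' gene-by-cell orientation regardless of the on-disk orientation, which is
#' inferred from the id counts; a square matrix is assumed to already be
#' gene-by-cell.
#'
#' @param dir Directory holding the triplet.
#' @return A sparse integer `dgCMatrix` with gene ids as rownames and
#'   barcodes as colnames. Symbols, if present, are attached as the
#'   `"symbols"` attribute.
#' @export
read_10x <- function(dir) {
  mtx <- find_triplet_file(dir, "matrix.mtx")
  feat <- find_triplet_file(dir, "features.tsv", alt = "genes.tsv")
  bc <- find_triplet_file(dir, "barcodes.tsv")

  m <- tryCatch(Matrix::readMM(mtx), error = function(e) {
    abort(sprintf("Failed to parse Matrix-Market file '%s': %s", mtx,
                  conditionMessage(e)))
  })
  if (nrow(m) == 0 || ncol(m) == 0) {
    abort(sprintf("Matrix file '%s' describes an empty matrix.", mtx))
  }
  features <- readr::read_tsv(feat, col_names = FALSE, col_types = readr::cols(
    .default = readr::col_character()))
  barcodes <- readr::read_tsv(bc, col_names = FALSE, col_types = readr::cols(
    .default = readr::col_character()))
  n_feat <- nrow(features)
  n_bc <- nrow(barcodes)

  if (nrow(m) == n_feat && ncol(m) == n_bc) {
    # gene x cell as written
  } else if (nrow(m) == n_bc && ncol(m) == n_feat) {
    m <- Matrix::t(m)
  } else {
    abort(sprintf(
      "Matrix is %d x %d but features has %d rows and barcodes %d rows.",
      nrow(m), ncol(m), n_feat, n_bc
    ))
  }
  if (length(m@x) && any(m@x != trunc(m@x))) {
    abort("Count matrix contains non-integer values.")
  }
  dimnames(m) <- list(features[[1]], barcodes[[1]])
  m <- validate_counts(m)
  if (ncol(features) >= 2) attr(m, "symbols") <- features[[2]]
  m
}

find_triplet_file <- function(dir, base, alt = NULL) {
  for (cand in c(base, paste0(base, ".gz"),
                 if (!is.null(alt)) c(alt, paste0(alt, ".gz")))) {
    p <- file.path(dir, cand)
    if (file.exists(p)) return(p)
  }
  abort(sprintf("No '%s[.gz]' found under '%s'.", base, dir))
}

#' Write a count matrix as a 10x-style Matrix-Market triplet
#'
#' @param counts Gene-by-cell count matrix with dimnames.
#' @param dir Output directory (created if missing).
#' @param symbols Optional gene symbols (defaults to the gene ids).
#' @param gzip Write gzipped files.
#' @return `dir`, invisibly.
#' @export
write_10x <- function(counts, dir, symbols = NULL, gzip = FALSE) {
  counts <- validate_counts(counts)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  symbols <- symbols %||% attr(counts, "symbols") %||% rownames(counts)
  stopifnot(length(symbols) == nrow(counts))
  ext <- if (gzip) ".gz" else ""
  mtx_path <- file.path(dir, paste0("matrix.mtx", ext))
  if (gzip) {
    tmp <- tempfile(fileext = ".mtx")
    Matrix::writeMM(counts, tmp)
    con_in <- file(tmp, "rb"); con_out <- gzfile(mtx_path, "wb")
    while (length(chunk <- readBin(con_in, "raw", 1048576L))) {
      writeBin(chunk, con_out)
    }
    close(con_in); close(con_out); unlink(tmp)
  } else {
    Matrix::writeMM(counts, mtx_path)
  }
  readr::write_tsv(
    tibble(id = rownames(counts), symbol = symbols,
           type = "Gene Expression"),
    file.path(dir, paste0("features.tsv", ext)), col_names = FALSE
  )
  readr::write_tsv(
    tibble(barcode = colnames(counts)),
    file.path(dir, paste0("barcodes.tsv", ext)), col_names = FALSE
  )
  invisible(dir)
}

#' Read a GMT gene-set collection
#'
#' Each tab-separated line is `name`, `description`, then member gene ids.
#' Duplicate members within a set are deduplicated; the description column
#' is discarded; duplicate set names are an error (the collection would be
#' ambiguous).
#'
#' @param path GMT file path.
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) abort(sprintf("GMT file '%s' is empty.", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3
  if (any(short)) {
    abort(sprintf("GMT line %d has fewer than 3 fields.", which(short)[1]))
  }
  names_ <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names_)) {
    abort(sprintf("Duplicate gene-set name '%s' in '%s'.",
                  names_[duplicated(names_)][1], path))
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  setNames(sets, names_)
}

#' Write a gene-set collection in GMT format
#'
#' @param collection Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional per-set descriptions (defaults to the names).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  stopifnot(is.list(collection), !is.null(names(collection)))
  descriptions <- descriptions %||% names(collection)
  lines <- vapply(seq_along(collection), function(i) {
    paste(c(names(collection)[i], descriptions[i], collection[[i]]),
          collapse = "\t")
  }, "")
  readr::write_lines(lines, path)
  invisible(path)
}
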