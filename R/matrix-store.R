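# Binary on-disk container for 2D matrices (full / sparse / symmetric) with
# selectable value types.  Fixed little-endian layout:
#
#   header, 48 bytes:
#     bytes  0- 3  magic "JMTX"
#     bytes  4- 5  format version, u16 (currently 1)
#     byte   6     kind, u8: 0 = FULL, 1 = SPARSE, 2 = SYMMETRIC
#     byte   7     value type, u8: 0 uint8, 1 int32, 2 uint32, 3 int64,
#                  4 float32, 5 float64
#     bytes  8-15  nrows, u64
#     bytes 16-23  ncols, u64
#     bytes 24-27  flags, u32: bit 0 rownames, bit 1 colnames, bit 2 comment
#     bytes 28-35  payload offset, u64 (= 48)
#     bytes 36-47  reserved (zero)
#
#   payload:
#     FULL       nrows*ncols values, row-major
#     SPARSE     per row: u32 nonzero count, then that many u32 column
#                indices (0-based, strictly increasing), then the values
#     SYMMETRIC  packed lower triangle including the diagonal, row-major:
#                n(n+1)/2 values (row i contributes entries (i,0)..(i,i))
#
#   metadata (only blocks whose flag is set, in this order):
#     rownames, colnames, comment — each string is u32 byte length + UTF-8.
#
# The layout contains no timestamps, so writing the same object twice is
# byte-identical.  Matrix indices are 32-bit unsigned, so each dimension
# must stay below 2^32.

JMTX_MAGIC <- charToRaw("JMTX")
JMTX_VERSION <- 1L
JMTX_HEADER_SIZE <- 48L
JMTX_KINDS <- c("FULL", "SPARSE", "SYMMETRIC")
JMTX_VALUE_TYPES <- c("uint8", "int32", "uint32", "int64", "float32", "float64")

#' Dense or sparse data matrix with a value-type tag
#'
#' Thin container pairing a numeric matrix (rows = individuals/cells,
#' columns = features/genes) with the value type it is serialized as and an
#' optional free-text comment. Sparse matrices are held as
#' [Matrix::dgCMatrix-class] and written in the SPARSE container layout;
#' dense matrices in the FULL layout.
#'
#' @param values numeric matrix or `dgCMatrix`; `dimnames` are preserved as
#'   the container's row/column names.
#' @param value_type one of `"uint8"`, `"int32"`, `"uint32"`, `"int64"`,
#'   `"float32"`, `"float64"`. Controls on-disk encoding only; in memory the
#'   values are R doubles.
#' @param comment optional single string stored in the file.
#' @return An object of class `data_matrix`.
#' @seealso [write_matrix()], [read_matrix()], [symmetric_matrix()]
#' @export
#' @examples
#' m <- data_matrix(matrix(1:6, 2, 3), value_type = "int32")
#' f <- tempfile(fileext = ".jmtx")
#' write_matrix(m, f)
#' peek_header(f)
data_matrix <- function(values, value_type = "float64", comment = "") {
  value_type <- match.arg(value_type, JMTX_VALUE_TYPES)
  if (inherits(values, "sparseMatrix")) {
    values <- methods::as(methods::as(values, "CsparseMatrix"), "generalMatrix")
    values <- Matrix::drop0(values)
  } else {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
  }
  structure(list(values = values, value_type = value_type,
                 comment = as.character(comment)[1]),
            class = "data_matrix")
}

#' Symmetric matrix stored by its lower triangle
#'
#' Container for an n-by-n symmetric matrix (typically a dissimilarity
#' matrix). On disk only the packed lower triangle, diagonal included, is
#' kept: n(n+1)/2 values.
#'
#' @param values symmetric numeric matrix.
#' @param value_type on-disk value type, see [data_matrix()].
#' @param comment optional single string.
#' @return An object of class `symmetric_matrix`.
#' @export
symmetric_matrix <- function(values, value_type = "float64", comment = "") {
  value_type <- match.arg(value_type, JMTX_VALUE_TYPES)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values))
    stop("a symmetric matrix must be square")
  if (!isTRUE(all.equal(values, t(values), tolerance = 0, check.attributes = FALSE)))
    stop("matrix is not symmetric")
  storage.mode(values) <- "double"
  structure(list(values = values, value_type = value_type,
                 comment = as.character(comment)[1]),
            class = "symmetric_matrix")
}

#' @export
#' @method as.matrix data_matrix
as.matrix.data_matrix <- function(x, ...) {
  if (inherits(x$values, "sparseMatrix")) as.matrix(x$values) else x$values
}

#' @export
#' @method as.matrix symmetric_matrix
as.matrix.symmetric_matrix <- function(x, ...) x$values

#' @export
dim.data_matrix <- function(x) dim(x$values)

#' @export
dim.symmetric_matrix <- function(x) dim(x$values)

#' @export
dimnames.data_matrix <- function(x) dimnames(x$values)

#' @export
dimnames.symmetric_matrix <- function(x) dimnames(x$values)

#' @export
#' @method print data_matrix
print.data_matrix <- function(x, ...) {
  kind <- if (inherits(x$values, "sparseMatrix")) "sparse" else "dense"
  cat(sprintf("<data_matrix> %d x %d, %s, value type %s\n",
              nrow(x$values), ncol(x$values), kind, x$value_type))
  if (nzchar(x$comment)) cat("comment:", x$comment, "\n")
  invisible(x)
}

#' @export
#' @method print symmetric_matrix
print.symmetric_matrix <- function(x, ...) {
  cat(sprintf("<symmetric_matrix> %d x %d, value type %s\n",
              nrow(x$values), ncol(x$values), x$value_type))
  if (nzchar(x$comment)) cat("comment:", x$comment, "\n")
  invisible(x)
}

## ---- low-level little-endian scalar I/O -----------------------------------

write_u8 <- function(con, x) writeBin(as.integer(x), con, size = 1L, endian = "little")
write_u16 <- function(con, x) writeBin(as.integer(x), con, size = 2L, endian = "little")

write_u32 <- function(con, x) {
  x <- as.double(x)
  xi <- ifelse(x >= 2^31, x - 2^32, x)
  writeBin(as.integer(xi), con, size = 4L, endian = "little")
}

write_u64 <- function(con, x) {
  x <- as.double(x)
  write_u32(con, x %% 2^32)
  write_u32(con, x %/% 2^32)
}

u32_from_raw <- function(r) {
  # r: raw vector, length multiple of 4
  v <- readBin(r, "integer", n = length(r) %/% 4L, size = 4L, endian = "little")
  v <- as.double(v)
  ifelse(v < 0, v + 2^32, v)
}

read_u32 <- function(con, n = 1L) {
  r <- readBin(con, "raw", n = 4L * n)
  if (length(r) < 4L * n) stop("truncated payload", call. = FALSE)
  u32_from_raw(r)
}

read_u64 <- function(con, n = 1L) {
  lohi <- read_u32(con, 2L * n)
  lo <- lohi[seq(1L, 2L * n, by = 2L)]
  hi <- lohi[seq(2L, 2L * n, by = 2L)]
  lo + hi * 2^32
}

## ---- value encoding per type ----------------------------------------------

validate_values <- function(v, value_type) {
  lim <- switch(value_type,
    uint8 = c(0, 255), int32 = c(-2^31, 2^31 - 1), uint32 = c(0, 2^32 - 1),
    int64 = c(-2^63, 2^63 - 1), float32 = c(-3.4028234663852886e38, 3.4028234663852886e38),
    float64 = NULL)
  if (is.null(lim)) return(invisible(TRUE))
  fin <- is.finite(v)
  bad <- fin & (v < lim[1] | v > lim[2])
  if (value_type %in% c("uint8", "int32", "uint32", "int64"))
    bad <- bad | (fin & v != round(v))
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("value %g at position %d overflows value type %s",
                 v[i], i, value_type), call. = FALSE)
  }
  invisible(TRUE)
}

write_values <- function(con, v, value_type) {
  v <- as.double(v)
  switch(value_type,
    uint8 = writeBin(as.raw(v), con),
    int32 = writeBin(as.integer(v), con, size = 4L, endian = "little"),
    uint32 = write_u32(con, v),
    int64 = {
      # R's %% / %/% floor toward -Inf, so lo is in [0, 2^32) and the signed
      # high word only needs a 2^32 shift; exact for |v| <= 2^53
      lo <- v %% 2^32
      hi <- v %/% 2^32
      hi <- ifelse(hi < 0, hi + 2^32, hi)
      n <- length(v)
      lohi <- double(2L * n)
      lohi[seq(1L, 2L * n, by = 2L)] <- lo
      lohi[seq(2L, 2L * n, by = 2L)] <- hi
      write_u32(con, lohi)
    },
    float32 = writeBin(v, con, size = 4L, endian = "little"),
    float64 = writeBin(v, con, size = 8L, endian = "little"))
  invisible(NULL)
}

read_values <- function(con, n, value_type) {
  out <- switch(value_type,
    uint8 = {
      r <- readBin(con, "raw", n = n)
      if (length(r) < n) stop("truncated payload", call. = FALSE)
      as.double(as.integer(r))
    },
    int32 = {
      r <- readBin(con, "raw", n = 4L * n)
      if (length(r) < 4L * n) stop("truncated payload", call. = FALSE)
      as.double(readBin(r, "integer", n = n, size = 4L, endian = "little"))
    },
    uint32 = read_u32(con, n),
    int64 = {
      lohi <- read_u32(con, 2L * n)
      lo <- lohi[seq(1L, 2L * n, by = 2L)]
      hi <- lohi[seq(2L, 2L * n, by = 2L)]
      hi <- ifelse(hi >= 2^31, hi - 2^32, hi)
      hi * 2^32 + lo
    },
    float32 = {
      r <- readBin(con, "raw", n = 4L * n)
      if (length(r) < 4L * n) stop("truncated payload", call. = FALSE)
      readBin(r, "double", n = n, size = 4L, endian = "little")
    },
    float64 = {
      r <- readBin(con, "raw", n = 8L * n)
      if (length(r) < 8L * n) stop("truncated payload", call. = FALSE)
      readBin(r, "double", n = n, size = 8L, endian = "little")
    })
  if (length(out) < n) stop("truncated payload", call. = FALSE)
  out
}

write_string_block <- function(con, strings) {
  for (s in strings) {
    b <- charToRaw(enc2utf8(s))
    write_u32(con, length(b))
    writeBin(b, con)
  }
}

read_string_block <- function(con, n) {
  out <- character(n)
  for (i in seq_len(n)) {
    len <- read_u32(con)
    b <- readBin(con, "raw", n = len)
    if (length(b) < len) stop("truncated metadata block", call. = FALSE)
    s <- rawToChar(b)
    Encoding(s) <- "UTF-8"
    out[i] <- s
  }
  out
}

## ---- header ----------------------------------------------------------------

parse_header <- function(raw48, path) {
  if (length(raw48) < JMTX_HEADER_SIZE || !identical(raw48[1:4], JMTX_MAGIC))
    stop(sprintf("'%s' is not a matrix container (bad magic)", path), call. = FALSE)
  version <- readBin(raw48[5:6], "integer", size = 2L, signed = FALSE, endian = "little")
  if (version != JMTX_VERSION)
    stop(sprintf("unsupported container version %d", version), call. = FALSE)
  kind_code <- as.integer(raw48[7])
  vt_code <- as.integer(raw48[8])
  if (kind_code > 2L || vt_code > 5L)
    stop("corrupt header: unknown kind or value type", call. = FALSE)
  nrows <- sum(u32_from_raw(raw48[9:16]) * c(1, 2^32))
  ncols <- sum(u32_from_raw(raw48[17:24]) * c(1, 2^32))
  flags <- u32_from_raw(raw48[25:28])
  payload_offset <- sum(u32_from_raw(raw48[29:36]) * c(1, 2^32))
  structure(list(
    magic = "JMTX", version = version,
    kind = JMTX_KINDS[kind_code + 1L],
    value_type = JMTX_VALUE_TYPES[vt_code + 1L],
    nrows = nrows, ncols = ncols,
    has_rownames = bitwAnd(flags, 1L) != 0L,
    has_colnames = bitwAnd(flags, 2L) != 0L,
    has_comment = bitwAnd(flags, 4L) != 0L,
    payload_offset = payload_offset), class = "matrix_header")
}

#' @export
#' @method print matrix_header
print.matrix_header <- function(x, ...) {
  cat(sprintf("<matrix_header> kind %s, value type %s, %0.f x %0.f\n",
              x$kind, x$value_type, x$nrows, x$ncols))
  cat(sprintf("  rownames: %s, colnames: %s, comment: %s\n",
              x$has_rownames, x$has_colnames, x$has_comment))
  invisible(x)
}

#' Inspect a matrix container without loading it
#'
#' Reads only the fixed 48-byte header of a binary matrix file, so the
#' dimensions, kind and value type of an arbitrarily large matrix can be
#' checked without touching its payload.
#'
#' @param path path to a file written by [write_matrix()].
#' @return A `matrix_header` with fields `kind`, `value_type`, `nrows`,
#'   `ncols`, `has_rownames`, `has_colnames`, `has_comment`,
#'   `payload_offset`.
#' @export
peek_header <- function(path) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path), call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  raw48 <- readBin(con, "raw", n = JMTX_HEADER_SIZE)
  parse_header(raw48, path)
}

## ---- write -----------------------------------------------------------------

#' Write a matrix to the binary container format
#'
#' Serializes a [data_matrix()] (dense = FULL layout, sparse = SPARSE layout)
#' or a [symmetric_matrix()] / dissimilarity matrix (SYMMETRIC layout: packed
#' lower triangle, n(n+1)/2 values) to a compact little-endian binary file.
#' Output is byte-identical for identical input. Values that cannot be
#' represented in the declared value type are rejected with an error naming
#' the offending element.
#'
#' @param x a `data_matrix` or `symmetric_matrix`.
#' @param path destination file path.
#' @return `path`, invisibly.
#' @seealso [read_matrix()], [peek_header()]
#' @export
write_matrix <- function(x, path) {
  UseMethod("write_matrix")
}

write_header <- function(con, kind, value_type, nrows, ncols, flags) {
  if (nrows >= 2^32 || ncols >= 2^32)
    stop("matrix dimensions must each be below 2^32 (indices are 32-bit unsigned)")
  writeBin(JMTX_MAGIC, con)
  write_u16(con, JMTX_VERSION)
  write_u8(con, match(kind, JMTX_KINDS) - 1L)
  write_u8(con, match(value_type, JMTX_VALUE_TYPES) - 1L)
  write_u64(con, nrows)
  write_u64(con, ncols)
  write_u32(con, flags)
  write_u64(con, JMTX_HEADER_SIZE)
  writeBin(rep(as.raw(0L), 12L), con)
}

meta_flags <- function(rn, cn, comment) {
  f <- 0L
  if (!is.null(rn)) f <- f + 1L
  if (!is.null(cn)) f <- f + 2L
  if (nzchar(comment)) f <- f + 4L
  f
}

write_metadata <- function(con, rn, cn, comment) {
  if (!is.null(rn)) write_string_block(con, rn)
  if (!is.null(cn)) write_string_block(con, cn)
  if (nzchar(comment)) write_string_block(con, comment)
}

#' @export
write_matrix.data_matrix <- function(x, path) {
  v <- x$values
  rn <- rownames(v)
  cn <- colnames(v)
  con <- file(path, "wb")
  on.exit(close(con))
  if (inherits(v, "sparseMatrix")) {
    tv <- methods::as(Matrix::t(v), "CsparseMatrix") # columns of tv = rows of v
    validate_values(tv@x, x$value_type)
    write_header(con, "SPARSE", x$value_type, nrow(v), ncol(v),
                 meta_flags(rn, cn, x$comment))
    p <- tv@p
    for (i in seq_len(nrow(v))) {
      sel <- if (p[i + 1L] > p[i]) (p[i] + 1L):p[i + 1L] else integer(0)
      write_u32(con, length(sel))
      if (length(sel)) {
        write_u32(con, tv@i[sel]) # already 0-based, ascending within row
        write_values(con, tv@x[sel], x$value_type)
      }
    }
  } else {
    validate_values(v, x$value_type)
    write_header(con, "FULL", x$value_type, nrow(v), ncol(v),
                 meta_flags(rn, cn, x$comment))
    write_values(con, as.vector(t(v)), x$value_type) # row-major
  }
  write_metadata(con, rn, cn, x$comment)
  invisible(path)
}

#' @export
write_matrix.symmetric_matrix <- function(x, path) {
  v <- x$values
  n <- nrow(v)
  nm <- rownames(v)
  # for a symmetric matrix, the column-major upper triangle equals the
  # row-major packed lower triangle
  packed <- v[upper.tri(v, diag = TRUE)]
  validate_values(packed, x$value_type)
  con <- file(path, "wb")
  on.exit(close(con))
  write_header(con, "SYMMETRIC", x$value_type, n, n, meta_flags(nm, NULL, x$comment))
  write_values(con, packed, x$value_type)
  write_metadata(con, nm, NULL, x$comment)
  invisible(path)
}

## ---- read ------------------------------------------------------------------

#' Read a matrix from the binary container format
#'
#' Inverse of [write_matrix()]: returns a [data_matrix()] (FULL and SPARSE
#' layouts) or a [symmetric_matrix()] (SYMMETRIC layout) with names, comment
#' and value-type tag restored. Files whose payload carries a metric tag in
#' the comment (as written by [pairwise_dissimilarity()]) come back as
#' dissimilarity matrices.
#'
#' @param path path to a container file.
#' @return A `data_matrix` or `symmetric_matrix`.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path), call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  h <- parse_header(readBin(con, "raw", n = JMTX_HEADER_SIZE), path)
  n <- h$nrows
  d <- h$ncols
  if (h$kind == "FULL") {
    vals <- read_values(con, n * d, h$value_type)
    v <- matrix(vals, nrow = n, ncol = d, byrow = TRUE)
  } else if (h$kind == "SPARSE") {
    rows <- vector("list", n)
    cols <- vector("list", n)
    xs <- vector("list", n)
    for (i in seq_len(n)) {
      cnt <- read_u32(con)
      if (cnt > 0) {
        ci <- read_u32(con, cnt)
        xv <- read_values(con, cnt, h$value_type)
        rows[[i]] <- rep.int(i, cnt)
        cols[[i]] <- ci + 1
        xs[[i]] <- xv
      }
    }
    v <- Matrix::sparseMatrix(i = unlist(rows) %||% integer(0),
                              j = unlist(cols) %||% integer(0),
                              x = unlist(xs) %||% double(0),
                              dims = c(n, d))
  } else { # SYMMETRIC
    packed <- read_values(con, n * (n + 1) / 2, h$value_type)
    v <- matrix(0, n, n)
    v[upper.tri(v, diag = TRUE)] <- packed
    low <- lower.tri(v)
    v[low] <- t(v)[low]
  }
  rn <- if (h$has_rownames) read_string_block(con, n) else NULL
  cn <- if (h$has_colnames) read_string_block(con, d) else NULL
  comment <- if (h$has_comment) read_string_block(con, 1L) else ""
  if (h$kind == "SYMMETRIC") {
    if (!is.null(rn)) dimnames(v) <- list(rn, rn)
    out <- symmetric_matrix(v, value_type = h$value_type, comment = comment)
    if (grepl("^metric=", comment))
      out <- as_dissimilarity(out, sub("^metric=", "", comment))
    out
  } else {
    if (!is.null(rn) || !is.null(cn)) dimnames(v) <- list(rn, cn)
    data_matrix(v, value_type = h$value_type, comment = comment)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
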