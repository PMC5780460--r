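# Boundary I/O: dense delimited connectivity matrices and time series, and
# JSON serialization of fitted mappings. All type invariants are enforced
# here, so nothing downstream ever sees a malformed matrix.

#' Read a connectivity matrix from dense delimited text
#'
#' Reads an \code{n x n} matrix from comma- or whitespace-delimited text
#' (autodetected), optionally with a header row of region labels mirrored in
#' a first label column. The matrix must be square and symmetric to within a
#' relative tolerance of \code{1e-8}; it is then symmetrized exactly as
#' \code{(X + t(X)) / 2}. Structural matrices must be non-negative;
#' functional matrices must have entries in \code{[-1, 1]}.
#'
#' @param path path to the file.
#' @param kind \code{"structural"}, \code{"functional"}, or \code{"generic"}
#'   (square symmetric, no range constraint — used for mapped matrices).
#' @return A numeric matrix, with \code{dimnames} when labels are present.
#' @export
read_matrix <- function(path, kind = c("structural", "functional", "generic")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  tokens <- strsplit(trimws(first), if (sep == ",") "," else "[[:space:]]+")[[1]]
  numeric_like <- !is.na(suppressWarnings(as.numeric(tokens))) |
    toupper(trimws(tokens)) %in% c("NAN", "NA", "INF", "-INF")
  has_header <- any(!numeric_like)
  if (has_header) {
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                            check.names = FALSE, stringsAsFactors = FALSE)
    X <- as.matrix(df)
    labels <- rownames(df)
    if (!identical(labels, colnames(df))) {
      stop("row and column labels disagree in ", path)
    }
  } else {
    X <- as.matrix(utils::read.table(path, header = FALSE, sep = sep))
    dimnames(X) <- NULL
    labels <- NULL
  }
  if (!is.numeric(X)) stop("non-numeric entries in ", path)
  if (nrow(X) != ncol(X)) stop("matrix in ", path, " is not square")
  if (any(is.na(X))) stop("NaN/NA entries in ", path)
  X <- check_square_symmetric(X, what = paste0("matrix in ", path))
  if (kind == "structural" && any(X < 0)) {
    stop("structural matrix in ", path, " has negative entries")
  }
  if (kind == "functional" && any(abs(X) > 1 + 1e-12)) {
    stop("functional matrix in ", path, " has entries outside [-1, 1]")
  }
  if (!is.null(labels)) dimnames(X) <- list(labels, labels)
  X
}

#' Write a matrix as dense delimited text
#'
#' Entries are written with 17 significant digits so that a read/write
#' round trip is faithful to better than \code{1e-12} relative. Labels
#' (dimnames), when present, become a header row and first column.
#'
#' @param X numeric matrix.
#' @param path output path.
#' @param sep field separator (default comma).
#' @export
write_matrix <- function(X, path, sep = ",") {
  stopifnot(is.matrix(X), is.numeric(X))
  fmt <- function(row) paste(sprintf("%.17g", row), collapse = sep)
  labels <- rownames(X)
  lines <- character(0)
  if (!is.null(labels)) {
    lines <- paste(c("region", labels), collapse = sep)
    body <- vapply(seq_len(nrow(X)),
                   function(i) paste(labels[i], fmt(X[i, ]), sep = sep),
                   character(1))
  } else {
    body <- vapply(seq_len(nrow(X)), function(i) fmt(X[i, ]), character(1))
  }
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read/write a regions-by-samples time series
#'
#' Same dense delimited dialect as the matrix files, without labels. The
#' loader rejects series with fewer than 2 regions or 4 samples, non-finite
#' values, or any zero-variance region.
#'
#' @param path file path.
#' @return For \code{read_bold_series}, an \code{M x L} numeric matrix.
#' @export
read_bold_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  X <- as.matrix(utils::read.table(path, header = FALSE, sep = sep))
  dimnames(X) <- NULL
  check_bold_series(X)
}

#' @rdname read_bold_series
#' @param signals \code{M x L} numeric matrix of signals.
#' @export
write_bold_series <- function(signals, path) {
  stopifnot(is.matrix(signals), is.numeric(signals))
  writeLines(vapply(seq_len(nrow(signals)),
                    function(i) paste(sprintf("%.17g", signals[i, ]), collapse = ","),
                    character(1)),
             path)
  invisible(path)
}

#' Normalize a structural matrix by its maximum weight
#'
#' Divides all entries by the overall maximum weight, so the largest entry
#' becomes exactly 1 and the zero pattern is preserved.
#'
#' @param S non-negative symmetric matrix with at least one positive entry.
#' @return The rescaled matrix.
#' @export
normalize_structural <- function(S) {
  S <- check_square_symmetric(S, what = "S")
  if (any(S < 0)) stop("structural matrix has negative entries")
  m <- max(S)
  if (m == 0) stop("cannot normalize an all-zero structural matrix")
  S / m
}

#' Serialize a fitted mapping to JSON
#'
#' Stores every model field at full double precision (~17 significant
#' digits); \code{read_mapping} reconstructs the fitted object, validating
#' dimensions and orthogonality on the way in.
#'
#' @param model a \code{\link{spectral_map}} or \code{\link{spectral_map_group}}
#'   object.
#' @param path output path (conventionally \code{.json}).
#' @export
write_mapping <- function(model, path) {
  if (inherits(model, "spectral_map")) {
    payload <- list(
      type = "individual",
      n = model$n, k = model$k, m = model$m,
      eigenvalue_scale = model$eigenvalue_scale,
      coefficients = as.numeric(model$coefficients),
      coefficients_scaled = as.numeric(model$coefficients_scaled),
      rotation = as.numeric(model$rotation),
      fit_residual = model$fit_residual
    )
  } else if (inherits(model, "spectral_map_group")) {
    payload <- list(
      type = "group",
      n = model$n, k = model$k, n_subjects_train = model$n_subjects_train,
      eigenvalue_scale = model$eigenvalue_scale,
      coefficients = as.numeric(model$coefficients),
      coefficients_scaled = as.numeric(model$coefficients_scaled),
      basis = as.numeric(model$basis),
      objective_trace = as.numeric(model$objective_trace),
      converged = isTRUE(model$converged)
    )
  } else {
    stop("model must be a spectral_map or spectral_map_group object")
  }
  bad <- vapply(payload[c("coefficients", if (payload$type == "individual") "rotation" else "basis")],
                function(x) any(!is.finite(x)), logical(1))
  if (any(bad)) stop("model contains non-finite fields; refusing to write")
  # I(17) significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_mapping
#' @return For \code{read_mapping}, the reconstructed model object.
#' @export
read_mapping <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- as.integer(p$n); k <- as.integer(p$k)
  if (p$type == "individual") {
    if (length(p$rotation) != n * n) stop("rotation has wrong shape in ", path)
    R <- matrix(p$rotation, n, n)
    check_orthogonal(R, tol = 1e-8, what = "stored rotation")
    if (length(p$coefficients) != k + 1L) stop("coefficient length != k + 1 in ", path)
    structure(list(
      coefficients = stats::setNames(as.numeric(p$coefficients), paste0("a", 0:k)),
      coefficients_scaled = as.numeric(p$coefficients_scaled),
      eigenvalue_scale = p$eigenvalue_scale,
      rotation = R, n = n, k = k, m = as.integer(p$m),
      fit_residual = p$fit_residual
    ), class = "spectral_map")
  } else if (p$type == "group") {
    if (length(p$basis) != n * n) stop("basis has wrong shape in ", path)
    Q <- matrix(p$basis, n, n)
    check_orthogonal(Q, tol = 1e-8, what = "stored basis")
    if (length(p$coefficients) != k + 1L) stop("coefficient length != k + 1 in ", path)
    structure(list(
      coefficients = stats::setNames(as.numeric(p$coefficients), paste0("c", 0:k)),
      coefficients_scaled = as.numeric(p$coefficients_scaled),
      eigenvalue_scale = p$eigenvalue_scale,
      basis = Q, n = n, k = k,
      n_subjects_train = as.integer(p$n_subjects_train),
      objective_trace = as.numeric(p$objective_trace),
      converged = isTRUE(p$converged)
    ), class = "spectral_map_group")
  } else {
    stop("unknown model type '", p$type, "' in ", path)
  }
}

check_orthogonal <- function(Q, tol = 1e-8, what = "matrix") {
  d <- max(abs(crossprod(Q) - diag(nrow(Q))))
  if (!is.finite(d) || d > tol) {
    stop(what, sprintf(" is not orthogonal (max |Q'Q - I| = %.3g)", d))
  }
  invisible(Q)
}
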