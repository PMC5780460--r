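# Shared fixtures for the specmap test suite. Everything is generated in
# code under fixed seeds; no stored data.

# Random dense symmetric matrix (not necessarily non-negative).
random_symmetric <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(rnorm(n * n), n, n)
  (X + t(X)) / 2
}

# Matrix power by repeated multiplication (independent of matrix_polynomial).
matrix_power <- function(S, l) {
  P <- diag(nrow(S))
  for (i in seq_len(l)) P <- P %*% S
  P
}

# Frobenius norm.
fnorm <- function(X) sqrt(sum(X * X))

# Path to the installed command-line script.
cli_path <- function() {
  p <- system.file("cli", "specmap.R", package = "specmap")
  stopifnot(nzchar(p))
  p
}

run_cli <- function(args) {
  # child Rscript processes must see the same library paths as this session
  # (the package may live in a non-default test library)
  withr::local_envvar(R_LIBS = paste(.libPaths(),
                                     collapse = .Platform$path.sep))
  out <- suppressWarnings(system2("Rscript", c(cli_path(), args),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  list(status = if (is.null(status)) 0L else status, output = out)
}
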