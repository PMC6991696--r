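# Internal helpers shared across modules.

GROUP_LEVELS <- c("NC", "CH", "HCC-N", "HCC-M")
SPLIT_LEVELS <- c("screen", "train", "valid", "blind")

#' @keywords internal
#' @noRd
abort_exopanel <- function(msg, class = "exopanel_error", ...) {
  rlang::abort(msg, class = c(class, "exopanel_error"), ...)
}

# Resolve a group label to the underlying clinical groups. "HCC" is an
# accepted composite meaning the union of HCC-N and HCC-M.
resolve_groups <- function(group) {
  out <- unlist(lapply(group, function(g) {
    if (identical(g, "HCC")) c("HCC-N", "HCC-M") else g
  }))
  bad <- setdiff(out, GROUP_LEVELS)
  if (length(bad) > 0) {
    abort_exopanel(
      sprintf("unknown group label(s): %s", paste(bad, collapse = ", ")),
      class = "exopanel_bad_group"
    )
  }
  out
}

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so simulation helpers do not perturb the session.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(expr)
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort_exopanel(
      sprintf("%s is missing column(s): %s", what, paste(missing, collapse = ", "))
    )
  }
  invisible(df)
}

ct_attr <- function(ct, name, override = NULL) {
  if (!is.null(override)) {
    return(override)
  }
  val <- attr(ct, name, exact = TRUE)
  if (is.null(val)) {
    abort_exopanel(sprintf(
      "`%s` not supplied and not carried as an attribute of the Ct table", name
    ))
  }
  val
}
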