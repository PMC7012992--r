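# Model-spec files (a small TOML dialect) and result serialisation.
# Dialect: [space] dim/lower/upper/x_b, [atoms] name = "description",
# [growth] expr = [...], [death] expr = "...", repeated [[birth]] tables with
# rate/state, repeated [[output]] tables with expr/label.

RESULT_SCHEMA_VERSION <- "1.0"

#' Load a model from a model-spec file
#'
#' @param path file path.
#' @return a [pspm_model()].
#' @export
load_model <- function(path) {
  doc <- parse_toml(path)
  need <- function(sec) {
    if (is.null(doc[[sec]])) stop(sprintf("%s: missing [%s] section", path, sec))
    doc[[sec]]
  }
  spc <- need("space")
  space <- istate_space(dim = spc$dim %||% 1L,
                        lower = unlist(spc$lower), upper = unlist(spc$upper),
                        x_b = unlist(spc$x_b))
  atoms <- lapply(names(doc$atoms %||% list()), function(nm)
    env_atom(nm, as.character(doc$atoms[[nm]])))
  gr <- need("growth")$expr
  if (!is.list(gr) && length(gr) == 1) gr <- list(gr)
  births <- lapply(doc[["birth"]] %||% list(), function(b)
    birth_term(b$rate, unlist(b$state), atoms = atom_names(atoms)))
  outputs <- lapply(doc[["output"]] %||% list(), function(o) o$expr)
  pspm_model(space, atoms, g = as.list(gr), mu = need("death")$expr,
             births = births, outputs = outputs,
             name = doc$meta$name %||% basename(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a model to a model-spec file
#'
#' Round-trips with [load_model()]: `load_model(save_model(m, f))` is
#' structurally equal to `m`.
#'
#' @param model a [pspm_model()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  sp <- model$space
  num <- function(v) paste0("[", paste(sprintf("%.17g", v), collapse = ", "), "]")
  lines <- c(
    "[meta]", sprintf('name = "%s"', model$name), "",
    "[space]", sprintf("dim = %d", sp$dim),
    sprintf("lower = %s", num(sp$lower)), sprintf("upper = %s", num(sp$upper)),
    sprintf("x_b = %s", num(sp$x_b)), "",
    "[atoms]",
    vapply(model$atoms, function(a) sprintf('%s = ""', a), character(1)), "",
    "[growth]",
    sprintf("expr = [%s]", paste(sprintf('"%s"', vapply(model$g, sep_format, character(1))),
                                 collapse = ", ")), "",
    "[death]", sprintf('expr = "%s"', sep_format(model$mu)))
  for (b in model$births)
    lines <- c(lines, "", "[[birth]]",
               sprintf('rate = "%s"', sep_format(b$rate_weight)),
               sprintf("state = %s", num(b$birth_state)))
  for (o in model$outputs)
    lines <- c(lines, "", "[[output]]", sprintf('expr = "%s"', sep_format(o)))
  writeLines(lines, path)
  invisible(path)
}

# minimal TOML-subset parser with line-numbered errors
parse_toml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  doc <- list()
  cur <- NULL       # list(path, is_array)
  perr <- function(i, msg) stop(sprintf("%s:%d: %s", path, i, msg), call. = FALSE)
  if (!length(lines) || all(!nzchar(trimws(lines))))
    perr(1L, "empty model-spec file")
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[\\[[A-Za-z0-9_.]+\\]\\]$", ln)) {
      sec <- gsub("^\\[\\[|\\]\\]$", "", ln)
      doc[[sec]] <- c(doc[[sec]] %||% list(), list(list()))
      cur <- list(path = sec, idx = length(doc[[sec]]))
    } else if (grepl("^\\[[A-Za-z0-9_.]+\\]$", ln)) {
      sec <- gsub("^\\[|\\]$", "", ln)
      if (is.null(doc[[sec]])) doc[[sec]] <- list()
      cur <- list(path = sec, idx = NA_integer_)
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.null(cur)) perr(i, "key outside any section")
      eq <- regexpr("=", ln, fixed = TRUE)
      key <- trimws(substr(ln, 1, eq - 1))
      if (!grepl("^[A-Za-z0-9_]+$", key)) perr(i, sprintf("bad key '%s'", key))
      val <- parse_toml_value(trimws(substr(ln, eq + 1, nchar(ln))),
                              function(msg) perr(i, msg))
      if (is.na(cur$idx)) doc[[cur$path]][[key]] <- val
      else doc[[cur$path]][[cur$idx]][[key]] <- val
    } else perr(i, sprintf("cannot parse line: '%s'", ln))
  }
  doc
}

parse_toml_value <- function(v, err) {
  if (grepl('^".*"$', v)) return(gsub('^"|"$', "", v))
  if (v %in% c("true", "false")) return(v == "true")
  if (grepl("^\\[.*\\]$", v)) {
    inner <- trimws(gsub("^\\[|\\]$", "", v))
    if (!nzchar(inner)) return(list())
    parts <- trimws(strsplit(inner, ",")[[1]])
    return(lapply(parts, parse_toml_value, err = err))
  }
  n <- suppressWarnings(as.numeric(v))
  if (!is.na(n)) return(if (grepl("^-?[0-9]+$", v)) as.integer(v) else n)
  if (v == "inf" || v == "Inf") return(Inf)
  err(sprintf("cannot parse value '%s'", v))
}

#' Serialise a reduction result to JSON
#'
#' Basis expressions as strings; K/H/M/Q as nested arrays of
#' {monomial, coefficient} terms; trace and certificate metadata included.
#'
#' @param result a `reduction_result`.
#' @param path destination (`.json`).
#' @return `path`, invisibly.
#' @export
save_result <- function(result, path) {
  out <- list(
    schema_version = RESULT_SCHEMA_VERSION,
    status = result$status,
    k = length(result$basis),
    basis = vapply(result$basis, sf_format, character(1)),
    provenance = result$provenance,
    K = if (!is.null(result$K)) em_to_list(result$K),
    H = if (!is.null(result$H)) em_to_list(result$H),
    M = if (!is.null(result$M)) em_to_list(result$M),
    Q = if (!is.null(result$Q)) em_to_list(result$Q),
    trace = result$trace,
    certificate = if (!is.null(result$certificate))
      list(seed = result$certificate$seed,
           n_points = length(result$certificate$points[[1]]),
           singular_values = result$certificate$singular_values))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a serialised reduction result
#'
#' @param path a `.json` written by [save_result()].
#' @return the parsed list (schema-checked).
#' @export
load_result <- function(path) {
  x <- jsonlite::read_json(path)
  if (!identical(x$schema_version, RESULT_SCHEMA_VERSION))
    stop("result schema version mismatch: ", x$schema_version)
  x
}

#' Write a trajectory as CSV
#'
#' Columns: `t`, one per output, and `cohort_count` when present.
#'
#' @param traj a trajectory from [integrate_reduced()] or
#'   [simulate_cohorts()].
#' @param path destination path.
#' @param labels optional output column names.
#' @return `path`, invisibly.
#' @export
save_trajectory <- function(traj, path, labels = NULL) {
  v <- traj_values(traj)
  if (is.null(labels)) labels <- paste0("N", seq_len(ncol(v)) - 1)
  df <- data.frame(t = traj$times, v)
  names(df) <- c("t", labels)
  if (!is.null(traj$cohort_count)) df$cohort_count <- traj$cohort_count
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
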