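#' Read an individual-size table
#'
#' Reads a CSV or TSV table with one row per individual and required
#' columns `site_id`, `individual_id`, `size` (an optional `size_units`
#' column is carried through as an attribute). Sizes must be positive and
#' `(site_id, individual_id)` pairs unique; violations are reported with
#' the offending data row number.
#'
#' @param path file path; `.csv` is read as comma-separated, anything else
#'   as tab-separated.
#' @return named list of numeric size vectors, one per site (names are the
#'   site ids, vector names the individual ids), with attributes `n_rows`
#'   and `size_units`.
#' @export
read_individuals_table <- function(path) {
  df <- read_table_auto(path)
  need <- c("site_id", "individual_id", "size")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$size <- as.numeric(df$size)
  bad <- which(!is.finite(df$size) | df$size <= 0)
  if (length(bad))
    stop(sprintf("non-positive or non-numeric size at row %d", bad[1]),
         call. = FALSE)
  key <- paste(df$site_id, df$individual_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop(sprintf("duplicate (site_id, individual_id) at row %d", dup[1]),
         call. = FALSE)
  out <- lapply(split(df, df$site_id), function(d)
    stats::setNames(d$size, d$individual_id))
  attr(out, "n_rows") <- nrow(df)
  attr(out, "size_units") <- if ("size_units" %in% names(df))
    unique(as.character(df$size_units)) else NA_character_
  out
}

read_table_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.csv$", path, ignore.case = TRUE))
    utils::read.csv(path, stringsAsFactors = FALSE)
  else
    utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write an individual-size table
#'
#' Inverse of [read_individuals_table()]: writes sizes at full double
#' precision (17 significant digits) so a write-read round trip is exact.
#'
#' @param sites named list of numeric size vectors (one element per site),
#'   or a single numeric vector (written as site `"s1"`).
#' @param path output path (`.csv` comma-separated, otherwise TSV).
#' @param size_units units label stored in the `size_units` column.
#' @return `path`, invisibly.
#' @export
write_individuals_table <- function(sites, path, size_units = "diameter") {
  if (is.numeric(sites)) sites <- list(s1 = sites)
  rows <- lapply(names(sites), function(sid) {
    v <- sites[[sid]]
    ids <- if (!is.null(names(v)) && all(nzchar(names(v)))) names(v)
    else sprintf("i%d", seq_along(v))
    data.frame(site_id = sid, individual_id = ids,
               size = sprintf("%.17g", v), size_units = size_units,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a species-abundance table
#'
#' Reads a CSV/TSV table with columns `site_id`, `species`, `count`
#' (non-negative integers).
#'
#' @inheritParams read_individuals_table
#' @return named list of named count vectors, one per site.
#' @export
read_abundance_table <- function(path) {
  df <- read_table_auto(path)
  need <- c("site_id", "species", "count")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$count <- as.numeric(df$count)
  bad <- which(!is.finite(df$count) | df$count < 0)
  if (length(bad))
    stop(sprintf("negative or non-numeric count at row %d", bad[1]),
         call. = FALSE)
  lapply(split(df, df$site_id), function(d)
    stats::setNames(d$count, d$species))
}

#' Generate seeded synthetic fixtures
#'
#' Writes a synthetic data table plus a JSON sidecar recording the
#' generating parameters (the ground truth for recovery tests). Kinds:
#'
#' * `"sad"`: species proportional abundances drawn iid from
#'   `Beta(alpha, beta)` and written as counts `round(x * J_ref)` in an
#'   abundance table. Counts are deliberately not renormalized to sum to
#'   `J_ref`, so refitting `count/J_ref` recovers the generating marginal.
#'   Params: `alpha`, `beta`, `n_species`, `J_ref` (default 1e5).
#' * `"sizes"`: individual sizes from the truncated Pareto. Params:
#'   `lambda`, `m0`, `mmax`, `n`.
#' * `"perturbed_sizes"`: a `"sizes"` draw followed by a pulse removal
#'   (scenario `"b"` = remove_small, `"d"` = remove_large) or a shifted
#'   re-draw (scenario `"c"`: sizes drawn from the post-press baseline
#'   with `lambda_post`, `mmax_post`). Params: those of `"sizes"` plus
#'   `scenario` and `intensity`/`threshold` (b/d) or
#'   `lambda_post`/`mmax_post` (c). The sidecar records pre- and
#'   post-perturbation parameters.
#'
#' @param kind fixture family.
#' @param params named list of generating parameters (see above).
#' @param seed integer seed (mandatory; fixtures are deterministic).
#' @param path output path for the data table; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @return invisibly, a list with `path`, `sidecar`, and the generated data.
#' @export
make_fixtures <- function(kind = c("sad", "sizes", "perturbed_sizes"),
                          params, seed, path) {
  kind <- match.arg(kind)
  if (missing(seed) || is.null(seed))
    stop("`seed` is mandatory for fixture generation", call. = FALSE)
  set.seed(seed)
  sidecar <- list(kind = kind, seed = seed, params = params)
  if (kind == "sad") {
    req_params(params, c("alpha", "beta", "n_species"))
    J_ref <- params$J_ref %||% 1e5
    x <- stats::rbeta(params$n_species, params$alpha, params$beta)
    counts <- pmax(1, round(x * J_ref))
    df <- data.frame(site_id = "s1",
                     species = sprintf("sp%03d", seq_along(counts)),
                     count = counts)
    sidecar$J_ref <- J_ref
    write_df(df, path)
  } else {
    req_params(params, c("lambda", "m0", "mmax", "n"))
    sizes <- rtrunc_pareto(params$n, params$lambda, params$m0, params$mmax)
    if (kind == "perturbed_sizes") {
      sc <- params$scenario
      if (is.null(sc) || !sc %in% c("b", "c", "d"))
        stop("`params$scenario` must be one of \"b\", \"c\", \"d\"",
             call. = FALSE)
      sidecar$pre <- list(lambda = params$lambda, m0 = params$m0,
                          mmax = params$mmax, n = params$n)
      if (sc %in% c("b", "d")) {
        spec <- perturbation(
          kind = if (sc == "b") "remove_small" else "remove_large",
          intensity = params$intensity %||% 0.9,
          threshold = params$threshold %||%
            stats::median(sizes) * (if (sc == "b") 1 else 2))
        sizes <- apply_perturbation(sizes, spec)
        sidecar$perturbation <- spec[c("kind", "intensity", "threshold")]
      } else {
        lam2 <- params$lambda_post %||% (params$lambda + 0.5)
        mm2 <- params$mmax_post %||% (params$mmax / 2)
        sizes <- rtrunc_pareto(params$n, lam2, params$m0, mm2)
        sidecar$perturbation <- list(kind = "press_shifted_baseline",
                                     lambda_post = lam2, mmax_post = mm2)
      }
      post <- fit_trunc_pareto(sizes, n_boot = 0)
      sidecar$post <- list(lambda = post$lambda, m0 = post$m0,
                           mmax = post$mmax, n = length(sizes))
    }
    write_individuals_table(list(s1 = sizes), path)
  }
  sidecar_path <- paste0(path, ".json")
  jsonlite::write_json(sidecar, sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(list(path = path, sidecar = sidecar_path, sidecar_data = sidecar))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

req_params <- function(params, need) {
  miss <- setdiff(need, names(params))
  if (length(miss))
    stop("missing fixture parameter(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
}

write_df <- function(df, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
}
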