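.header_lines <- function(traj = NULL, seed = NULL, config_hash = NULL) {
  c(sprintf("# funcld %s", as.character(utils::packageVersion("funcld"))),
    if (!is.null(seed)) sprintf("# seed: %s", seed),
    if (!is.null(config_hash)) sprintf("# config_hash: %s", config_hash))
}

.config_hash <- function(x) {
  # stable short hash of a serialized configuration (djb2 over the bytes)
  raw <- serialize(x, NULL, version = 2)
  h <- 5381
  for (b in as.integer(raw)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

.write_tsv <- function(df, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  as_tibble(read.delim(path, sep = "\t", comment.char = "#",
                       stringsAsFactors = FALSE))
}

#' Write / read a chain population dump
#'
#' Tab-separated, UTF-8, one row per macromolecule with columns `chain_id`,
#' `cl`, `n1`, `n2`, `terminal`, `status`, `branch_count`; a comment header
#' records the package version, seed and configuration hash so dumps are
#' traceable.
#'
#' @param traj A `kmc_trajectory` (or a population tibble).
#' @param path Output / input file path.
#' @param seed Seed recorded in the header (taken from `traj` if available).
#' @return `write_population()` returns `path` invisibly;
#'   `read_population()` returns a population tibble.
#' @export
write_population <- function(traj, path, seed = NULL) {
  pop <- if (inherits(traj, "kmc_trajectory")) traj$population else as_tibble(traj)
  if (inherits(traj, "kmc_trajectory")) {
    seed <- seed %||% traj$seed
    hash <- .config_hash(traj$run)
  } else hash <- NULL
  cols <- intersect(c("chain_id", "cl", "n1", "n2", "terminal", "status",
                      "branch_count", "sequence"), names(pop))
  invisible(.write_tsv(pop[cols], path, .header_lines(seed = seed, config_hash = hash)))
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  pop <- .read_tsv(path)
  need <- c("cl", "n1", "n2", "status")
  if (!all(need %in% names(pop))) {
    abort(sprintf("population file %s lacks columns: %s", path,
                  paste(setdiff(need, names(pop)), collapse = ", ")))
  }
  pop$status <- factor(pop$status, levels = .STATUS_LEVELS)
  pop$func <- pop$n2
  if (is.null(pop$branch_count)) pop$branch_count <- 0L
  if (is.null(pop$chain_id)) pop$chain_id <- seq_len(nrow(pop))
  pop
}

#' Export a FUNC-CLD
#'
#' Writes the long-format table (`cl`, `func`, `n`, `fraction`) and, with
#' `dense = TRUE`, also the dense CL x FUNC matrix (rows CL, columns FUNC)
#' as `<path basename>_dense.tsv`.
#'
#' @param fc A `func_cld`.
#' @param path Output path for the long-format TSV.
#' @param dense Also write the dense matrix.
#' @return `path`, invisibly.
#' @export
write_func_cld <- function(fc, path, dense = TRUE) {
  .write_tsv(as_tibble(fc), path, .header_lines())
  if (dense) {
    m <- as.matrix(fc)
    dpath <- sub("(\\.tsv)?$", "_dense.tsv", path)
    df <- data.frame(cl = as.integer(rownames(m)), m, check.names = FALSE)
    .write_tsv(df, dpath, .header_lines())
  }
  invisible(path)
}

#' Distribution summary of a chain population
#'
#' The analysis half of the pipeline: builds the FUNC-CLD, its marginals,
#' moments and quality metrics from a population (simulated in-session or
#' re-read from a dump). A dump re-read through [read_population()]
#' reproduces the simulate-time summary exactly.
#'
#' @param population Population tibble or `kmc_trajectory`.
#' @param thresholds A [quality_thresholds()].
#' @return One-row tibble with `n_chains`, `x_n`, `x_w`, `dispersity`,
#'   `mu_funcd`, `sigma_funcd`, `cv_funcd`, `f_nonfunctionalized`,
#'   `macromonomer_fraction`, `branched_fraction`, `mode_cl`, `mode_func`,
#'   `label`.
#' @export
analyze_population <- function(population, thresholds = quality_thresholds()) {
  if (inherits(population, "kmc_trajectory")) population <- population$population
  fc <- build_func_cld(population)
  mg <- marginals(fc)
  cm <- cld_moments(mg$cld)
  fm <- funcd_moments(mg$funcd)
  sp <- species_fractions(population)
  md <- cld_mode(fc)
  cv <- if (fm$mu > 0) fm$sigma / fm$mu else NA_real_
  f0 <- fraction_nonfunctionalized(mg$funcd)
  tibble(n_chains = attr(fc, "n_chains"), x_n = cm$x_n, x_w = cm$x_w,
         dispersity = cm$dispersity, mu_funcd = fm$mu, sigma_funcd = fm$sigma,
         cv_funcd = cv, f_nonfunctionalized = f0,
         macromonomer_fraction = sp$macromonomer_fraction,
         branched_fraction = sp$branched_fraction,
         mode_cl = md$cl, mode_func = md$func,
         label = classify_quality(cv, f0, thresholds))
}

#' Write a JSON summary document
#'
#' @param summary A one-row tibble (e.g. from [analyze_population()]) or a
#'   named list.
#' @param path Output path.
#' @param seed,config_hash Optional provenance fields added to the document.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path, seed = NULL, config_hash = NULL) {
  doc <- as.list(as.data.frame(summary))
  doc <- lapply(doc, function(v) if (is.factor(v)) as.character(v) else v)
  doc$funcld_version <- as.character(utils::packageVersion("funcld"))
  if (!is.null(seed)) doc$seed <- seed
  if (!is.null(config_hash)) doc$config_hash <- config_hash
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
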