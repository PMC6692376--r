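#' Read a chemistry / run configuration file
#'
#' Parses the YAML configuration schema: a `chemistry` key (`crop` or
#' `atrp`), a `monomers` list (two entries, `id`/`name`/`functional`),
#' rate-coefficient sections `initiation`, `propagation`, `transfer`,
#' `macropropagation`, optional `terminator` and `atrp`, each entry an
#' `{A, Ea}` pair (`A` in L mol^-1 s^-1 for bimolecular channels, `Ea` in
#' J mol^-1), and an optional `conditions` section mapping onto
#' [run_config()] fields (plus `events` for feeds/quench and `ablations`).
#' Unknown keys and malformed entries are rejected with their location;
#' all problems are reported together.
#'
#' @param path Path to a YAML configuration file.
#' @return A list with elements `model` ([kinetic_model()]) and `run`
#'   ([run_config()] or `NULL` when the file has no `conditions` section).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  problems <- character()
  note <- function(...) problems <<- c(problems, sprintf(...))

  known_top <- c("name", "chemistry", "units", "provenance", "monomers",
                 "initiation", "propagation", "transfer", "macropropagation",
                 "terminator", "atrp", "conditions")
  for (k in setdiff(names(cfg), known_top)) note("unknown top-level key '%s'", k)

  chem <- cfg$chemistry
  if (is.null(chem) || !chem %in% c("crop", "atrp")) {
    note("chemistry must be 'crop' or 'atrp'")
  }
  mono <- cfg$monomers
  if (is.null(mono) || length(mono) != 2) {
    note("monomers: exactly two entries required")
    ids <- c("M1", "M2")
    monomers <- monomer_set(ids)
  } else {
    ids <- vapply(mono, function(m) m$id %||% NA_character_, "")
    fun <- vapply(mono, function(m) isTRUE(m$functional), TRUE)
    nms <- vapply(mono, function(m) m$name %||% m$id %||% "", "")
    if (any(is.na(ids))) note("monomers: every entry needs an 'id'")
    if (sum(fun) != 1) note("monomers: exactly one must have functional: true")
    if (!is.null(mono[[2]]) && !isTRUE(mono[[2]]$functional)) {
      note("monomers: by convention monomer 2 (the second entry) is the functional one")
    }
    monomers <- tibble(id = ids, name = nms, functional = fun)
  }

  pair <- function(x, where) {
    if (is.null(x)) return(NULL)
    if (!is.list(x) || is.null(x$A)) {
      note("%s: expected an {A, Ea} pair", where)
      return(NULL)
    }
    if (!is.numeric(x$A) || x$A < 0) note("%s: A must be numeric >= 0", where)
    if (!is.null(x$Ea) && (!is.numeric(x$Ea) || x$Ea < 0)) {
      note("%s: Ea must be numeric >= 0", where)
    }
    if (is.numeric(x$A) && x$A == 0) return(NULL)
    tryCatch(arrhenius_params(x$A, x$Ea %||% 0), error = function(e) {
      note("%s: %s", where, conditionMessage(e)); NULL
    })
  }
  per_monomer <- function(section, nm) {
    lapply(ids, function(id) pair(section[[id]], sprintf("%s.%s", nm, id)))
  }
  matrix_section <- function(section, nm) {
    if (is.null(section)) return(NULL)
    lapply(ids, function(i) {
      lapply(ids, function(j) pair(section[[i]][[j]], sprintf("%s.%s.%s", nm, i, j)))
    })
  }

  k_i <- per_monomer(cfg$initiation, "initiation")
  if (is.null(cfg$initiation)) note("initiation section is required")
  k_p <- matrix_section(cfg$propagation, "propagation")
  if (is.null(k_p)) note("propagation section is required")
  k_trM <- matrix_section(cfg$transfer, "transfer")
  k_pm <- if (is.null(cfg$macropropagation)) NULL else {
    per_monomer(cfg$macropropagation, "macropropagation")
  }
  k_t <- pair(cfg$terminator, "terminator")
  atrp <- NULL
  if (identical(chem, "atrp")) {
    ab <- cfg$atrp
    if (is.null(ab)) {
      note("chemistry 'atrp' requires an atrp section")
    } else {
      atrp <- list(k_a_i = pair(ab$k_a_i, "atrp.k_a_i"),
                   k_da_i = pair(ab$k_da_i, "atrp.k_da_i"),
                   k_a = pair(ab$k_a, "atrp.k_a"),
                   k_da = pair(ab$k_da, "atrp.k_da"),
                   k_t_rad = pair(ab$k_t_rad, "atrp.k_t_rad"),
                   termination_mode = ab$termination_mode %||% "combination")
    }
  } else if (!is.null(cfg$atrp)) {
    note("atrp section present but chemistry is not 'atrp'")
  }

  run <- NULL
  if (!is.null(cfg$conditions)) {
    cond <- cfg$conditions
    known_cond <- c("temperature_C", "total_monomer_conc_M", "target_dp",
                    "f2_0", "n_chains", "stop_conversion", "events",
                    "ablations", "activator_eq", "deactivator_eq", "seed")
    for (k in setdiff(names(cond), known_cond)) note("unknown conditions key '%s'", k)
    if (is.null(cond$temperature_C)) note("conditions.temperature_C is required")
    if (!is.null(cond$total_monomer_conc_M) && cond$total_monomer_conc_M <= 0) {
      note("conditions.total_monomer_conc_M must be positive")
    }
    if (!is.null(cond$f2_0) && (cond$f2_0 < 0 || cond$f2_0 > 1)) {
      note("conditions.f2_0 must be in [0, 1]")
    }
    feed <- NULL
    quench_at <- NULL
    for (ev in cond$events %||% list()) {
      if (identical(ev$type, "quench")) {
        quench_at <- list(trigger = ev$trigger %||% "conversion", at = ev$at)
      } else if (identical(ev$type, "feed")) {
        feed <- dplyr::bind_rows(feed, tibble(
          species = ev$species, amount_eq = ev$amount_eq,
          trigger = ev$trigger %||% "conversion", at = ev$at))
      } else {
        note("unknown event type '%s'", ev$type %||% "<missing>")
      }
    }
    abl <- cond$ablations %||% list()
    if (!length(problems)) {
      run <- run_config(
        temperature = cond$temperature_C,
        total_monomer_conc = cond$total_monomer_conc_M %||% 3,
        target_dp = cond$target_dp %||% 100,
        f2_0 = cond$f2_0 %||% 0.5,
        n_chains = cond$n_chains %||% 1e4,
        stop_conversion = cond$stop_conversion %||% 0.99,
        feed_events = feed,
        quench_at = quench_at,
        ideal_mode = isTRUE(abl$ideal_mode),
        disable_transfer = isTRUE(abl$disable_transfer),
        disable_reinitiation_after_transfer =
          isTRUE(abl$disable_reinitiation_after_transfer),
        disable_macropropagation = isTRUE(abl$disable_macropropagation),
        activator_eq = cond$activator_eq %||% 1,
        deactivator_eq = cond$deactivator_eq %||% 0
      )
    }
  }

  if (length(problems)) {
    abort(paste0("invalid configuration ", path, ":\n  - ",
                 paste(problems, collapse = "\n  - ")))
  }
  model <- kinetic_model(monomers = monomers, k_i = k_i, k_p = k_p,
                         k_trM = k_trM, k_pm = k_pm, k_t = k_t, atrp = atrp,
                         name = cfg$name %||% basename(path))
  list(model = model, run = run)
}

#' Shipped chemistry presets
#'
#' `preset_names()` lists the bundled scenario configurations;
#' `preset_path()` resolves one to its YAML file; `preset_model()` /
#' `preset_run()` load its kinetic model / default run conditions. The CROP
#' presets carry literature homo-propagation coefficients together with
#' clearly labeled placeholder Arrhenius pairs for the remaining channels
#' (provenance notes in each file); the ATRP presets are literature-guided
#' placeholders. See the package vignette for how the placeholder values
#' were constructed.
#'
#' @param name Preset name, one of `preset_names()`.
#' @return `preset_model()`: a [kinetic_model()]; `preset_run()`: a
#'   [run_config()]; `preset_path()`: a file path.
#' @export
preset_names <- function() {
  sub("\\.yaml$", "", dir(system.file("extdata", "presets", package = "funcld"),
                          pattern = "\\.yaml$"))
}

#' @rdname preset_names
#' @export
preset_path <- function(name) {
  p <- system.file("extdata", "presets", paste0(name, ".yaml"),
                   package = "funcld")
  if (p == "") {
    abort(sprintf("unknown preset '%s' (available: %s)", name,
                  paste(preset_names(), collapse = ", ")))
  }
  p
}

#' @rdname preset_names
#' @export
preset_model <- function(name) read_config(preset_path(name))$model

#' @rdname preset_names
#' @export
preset_run <- function(name) {
  run <- read_config(preset_path(name))$run
  if (is.null(run)) abort(sprintf("preset '%s' has no conditions section", name))
  run
}
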