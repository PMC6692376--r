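#' Define a two-monomer set
#'
#' @param ids Character vector of two monomer identifiers. By package
#'   convention monomer 1 is the non-functional comonomer and monomer 2 the
#'   functional one.
#' @param names Display names (defaults to `ids`).
#' @param functional Logical vector flagging the functional comonomer;
#'   exactly one of the two must be `TRUE`.
#' @return A tibble with columns `id`, `name`, `functional`.
#' @export
monomer_set <- function(ids, names = ids, functional = c(FALSE, TRUE)) {
  if (length(ids) != 2) abort("exactly two monomers are supported")
  if (sum(functional) != 1) {
    abort("exactly one monomer in a two-monomer system must be functional")
  }
  tibble(id = as.character(ids), name = as.character(names),
         functional = as.logical(functional))
}

.as_entry <- function(x, what) {
  if (is.null(x)) return(NULL)
  if (is.numeric(x) && length(x) == 1 && x == 0) return(NULL)
  if (inherits(x, "arrhenius")) return(x)
  if (is.list(x) && !is.null(x$A)) return(arrhenius_params(x$A, x$Ea %||% 0))
  abort(sprintf("%s must be an arrhenius_params() object, 0, or NULL", what))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.entry_matrix <- function(x, what) {
  if (is.null(x)) {
    return(list(list(NULL, NULL), list(NULL, NULL)))
  }
  if (!is.list(x) || length(x) != 2 || !all(vapply(x, length, 1L) == 2)) {
    abort(sprintf("%s must be a 2x2 nested list (terminal x monomer)", what))
  }
  lapply(seq_len(2), function(i) {
    lapply(seq_len(2), function(j) {
      .as_entry(x[[i]][[j]], sprintf("%s[[%d]][[%d]]", what, i, j))
    })
  })
}

#' Assemble a kinetic model for a copolymerization chemistry
#'
#' Collects the Arrhenius-parameterized rate coefficients of every reaction
#' channel of a two-monomer chain-growth copolymerization under the terminal
#' model: chain initiation `k_i[j]`, the propagation matrix `k_p[[i]][[j]]`
#' (active chain with terminal unit `i` adds monomer `j`), chain transfer to
#' monomer `k_trM[[i]][[j]]`, macropropagation `k_pm[i]` (terminal-unit
#' resolved; macromonomer reactivity is assumed independent of macromonomer
#' length and composition), an optional terminator coefficient `k_t`, and an
#' optional ATRP exchange/termination block. Absent side reactions are
#' written as `NULL` (or `0`) and become exact zeros.
#'
#' @param monomers A [monomer_set()] tibble (monomer 2 functional).
#' @param k_i List of two [arrhenius_params()], chain initiation per monomer.
#' @param k_p 2x2 nested list of [arrhenius_params()], propagation.
#' @param k_trM 2x2 nested list, chain transfer to monomer; `NULL` for none.
#' @param k_pm List of two entries, macropropagation per terminal unit;
#'   `NULL` for none.
#' @param k_t Optional terminator-addition coefficient (kinetic quench
#'   channel; off by default, quenching is normally an instantaneous event).
#' @param atrp Optional list with entries `k_a_i`, `k_da_i` (initiator
#'   activation/deactivation), `k_a`, `k_da` (dormant-chain exchange),
#'   `k_t_rad` (radical termination), and `termination_mode`
#'   (`"combination"` or `"disproportionation"`). When present the chemistry
#'   is ATRP and `k_i` is the addition of the activated initiator radical to
#'   monomer.
#' @param name Optional label for the model.
#' @return An object of class `kinetic_model`.
#' @export
kinetic_model <- function(monomers, k_i, k_p, k_trM = NULL, k_pm = NULL,
                          k_t = NULL, atrp = NULL, name = "custom") {
  stopifnot(is.data.frame(monomers), nrow(monomers) == 2)
  if (!isTRUE(monomers$functional[2]) || isTRUE(monomers$functional[1])) {
    abort("by convention monomer 1 must be non-functional and monomer 2 functional")
  }
  if (!is.list(k_i) || length(k_i) != 2) abort("`k_i` must be a list of two entries")
  k_i <- lapply(seq_len(2), function(j) .as_entry(k_i[[j]], sprintf("k_i[[%d]]", j)))
  k_p <- .entry_matrix(k_p, "k_p")
  for (i in 1:2) for (j in 1:2) {
    if (is.null(k_p[[i]][[j]])) abort("all four propagation entries must be present")
  }
  k_trM <- .entry_matrix(k_trM, "k_trM")
  if (!is.null(k_pm) && (!is.list(k_pm) || length(k_pm) != 2)) {
    abort("`k_pm` must be NULL or a list of two entries")
  }
  k_pm <- if (is.null(k_pm)) list(NULL, NULL) else {
    lapply(seq_len(2), function(i) .as_entry(k_pm[[i]], sprintf("k_pm[[%d]]", i)))
  }
  k_t <- .as_entry(k_t, "k_t")
  if (!is.null(atrp)) {
    need <- c("k_a_i", "k_da_i", "k_a", "k_da", "k_t_rad")
    miss <- setdiff(need, names(atrp))
    if (length(miss)) abort(paste("atrp block missing:", paste(miss, collapse = ", ")))
    atrp[need] <- lapply(need, function(nm) .as_entry(atrp[[nm]], nm))
    atrp$termination_mode <- match.arg(atrp$termination_mode %||% "combination",
                                       c("combination", "disproportionation"))
  }
  structure(list(monomers = monomers, k_i = k_i, k_p = k_p, k_trM = k_trM,
                 k_pm = k_pm, k_t = k_t, atrp = atrp, name = name),
            class = "kinetic_model")
}

#' @export
print.kinetic_model <- function(x, ...) {
  chem <- if (is.null(x$atrp)) "CROP-type (cationic/living)" else "ATRP"
  cat(sprintf("<kinetic_model> %s — %s\n", x$name, chem))
  cat(sprintf("  monomers: %s (non-functional), %s (functional)\n",
              x$monomers$id[1], x$monomers$id[2]))
  has <- function(e) !is.null(e)
  cat(sprintf("  side channels: transfer %s, macropropagation %s, terminator %s\n",
              if (any(vapply(unlist(x$k_trM, recursive = FALSE), has, TRUE))) "on" else "off",
              if (any(vapply(x$k_pm, has, TRUE))) "on" else "off",
              if (has(x$k_t)) "on" else "off"))
  invisible(x)
}

.rate0 <- function(entry, temperature) {
  if (is.null(entry)) 0 else arrhenius_rate(entry, temperature)
}

#' Terminal-model reactivity ratios
#'
#' Computes `r1 = k_p(2->2) / k_p(2->1)` and `r2 = k_p(1->1) / k_p(1->2)`
#' at the given temperature, with monomer 2 the functional comonomer, so
#' that `r1` multiplies the squared functional-monomer feed fraction in the
#' Mayo-Lewis equation (see [mayo_lewis_instantaneous()]).
#'
#' @param model A [kinetic_model()].
#' @param temperature Absolute temperature, K.
#' @return A tibble with one row and columns `r1`, `r2`.
#' @export
reactivity_ratios <- function(model, temperature) {
  kp <- function(i, j) .rate0(model$k_p[[i]][[j]], temperature)
  if (kp(2, 1) == 0 || kp(1, 2) == 0) {
    abort("cross-propagation coefficients are zero: reactivity ratios undefined")
  }
  tibble(r1 = kp(2, 2) / kp(2, 1), r2 = kp(1, 1) / kp(1, 2))
}

#' Kinetic model of an ideal statistical copolymerization
#'
#' All four propagation coefficients equal, no side reactions. Combined with
#' `ideal_mode = TRUE` in [run_config()] (instantaneous initiation of all
#' chains) this is the theoretical reference case of a perfect statistical
#' copolymerization.
#'
#' @param k_p A single [arrhenius_params()] shared by all propagation steps.
#' @return A `kinetic_model`.
#' @export
ideal_model <- function(k_p = arrhenius_params(0.15)) {
  kinetic_model(
    monomers = monomer_set(c("M1", "M2")),
    k_i = list(k_p, k_p),
    k_p = list(list(k_p, k_p), list(k_p, k_p)),
    name = "ideal"
  )
}
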