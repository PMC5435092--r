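#' Atopic case definitions: ICPC diagnosis codes and ATC prescription proxies
#'
#' The default case definitions map each disorder to the ICPC-1 code its
#' episodes of care carry and to the ATC prefixes of prescriptions accepted
#' as evidence of clinically relevant disease:
#'
#' * atopic eczema: ICPC S87; ATC D07 (dermatological corticosteroids);
#' * asthma: ICPC R96; ATC R03 (drugs for obstructive airway diseases);
#' * allergic rhinitis: ICPC R97; ATC R01AC (nasal antiallergic agents,
#'   excl. corticosteroids), R01AD (nasal corticosteroids) and R06
#'   (systemic antihistamines).
#'
#' Prescription matching is by ATC prefix, so any code beginning with a
#' listed prefix qualifies (e.g. `R03AC02` matches `R03`).
#'
#' @param path Optional path to a YAML file with the same structure as the
#'   bundled `definitions.yaml` (one entry per disorder with `icpc` and
#'   `atc` fields).  `NULL` uses the built-in defaults.
#' @return A tibble with columns `disorder`, `icpc`, and `atc`
#'   (a list-column of character prefix vectors).
#' @examples
#' atopic_definitions()
#' @export
atopic_definitions <- function(path = NULL) {
  if (is.null(path)) {
    defs <- list(
      eczema   = list(icpc = "S87", atc = "D07"),
      asthma   = list(icpc = "R96", atc = "R03"),
      rhinitis = list(icpc = "R97", atc = c("R01AC", "R01AD", "R06"))
    )
  } else {
    if (!file.exists(path)) {
      abort(sprintf("definitions file not found: %s", path))
    }
    defs <- yaml::read_yaml(path)
  }
  out <- tibble(
    disorder = names(defs),
    icpc = vapply(defs, function(d) as.character(d$icpc), character(1)),
    atc = lapply(defs, function(d) toupper(as.character(d$atc)))
  )
  validate_definitions(out)
  out
}

validate_definitions <- function(defs) {
  if (nrow(defs) == 0) abort("configuration error: no disorder definitions.")
  if (any(!nzchar(defs$icpc)) || anyNA(defs$icpc)) {
    abort("configuration error: every definition needs a non-empty ICPC code.")
  }
  if (anyDuplicated(defs$icpc)) {
    abort("configuration error: duplicate ICPC codes across definitions.")
  }
  for (i in seq_len(nrow(defs))) {
    p <- defs$atc[[i]]
    if (length(p) == 0 || any(!nzchar(p))) {
      abort(sprintf("configuration error: disorder '%s' has no ATC prefixes.",
                    defs$disorder[i]))
    }
    # prefixes must themselves be lexically valid (possibly truncated) ATC
    if (any(!grepl("^[A-Z]([0-9]{2}([A-Z]([A-Z]([0-9]{2})?)?)?)?$", p))) {
      abort(sprintf("configuration error: disorder '%s' has a malformed ATC prefix.",
                    defs$disorder[i]))
    }
  }
  invisible(defs)
}

# TRUE where `atc` starts with any of `prefixes`
atc_matches <- function(atc, prefixes) {
  if (length(atc) == 0) return(logical(0))
  hit <- rep(FALSE, length(atc))
  for (p in prefixes) hit <- hit | startsWith(atc, p)
  hit
}
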