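#' Default domain-label alias table
#'
#' antiSMASH spells some domain symbols differently between the `NRPS_PKS`
#' and `sec_met_domain` qualifier vocabularies (e.g. `PP-binding` vs
#' `PP_bind`, `Condensation_LCL` vs the figure symbol `Cond_LCL`). Labels are
#' first normalized (whitespace/hyphens to underscores) and then mapped
#' through this alias table so that both vocabularies land on one canonical
#' token per domain.
#'
#' @return Named character vector mapping normalized spellings to canonical
#'   tokens.
#' @export
domain_aliases <- function() {
  c(
    PP_binding          = "PP_bind",
    PKS_PP              = "PP_bind",
    ACP_beta            = "ACP",
    Condensation_LCL    = "Cond_LCL",
    Condensation_DCL    = "Cond_DCL",
    Condensation_Starter = "Cond_Starter",
    Condensation_Dual   = "Cond_Dual",
    AMP_binding_C       = "AMP_binding",
    Thioesterase        = "TE",
    PKS_KS_Hybrid_KS    = "Hyb_KS",
    PKS_KS_Iterative_KS = "Itr_KS",
    PKS_KS_Modular_KS   = "Mod_KS",
    PKS_KS_Trans_AT_KS  = "Trans_AT_KS",
    PKS_AT              = "AT",
    PKS_KR              = "KR",
    PKS_DH              = "DH",
    PKS_ER              = "ER"
  )
}

#' Normalize a domain label to the canonical vocabulary
#'
#' Strips surrounding whitespace, converts internal whitespace and hyphens to
#' underscores, collapses runs of underscores, rewrites antiSMASH subtype
#' parentheses (`Condensation(LCL)` becomes `Condensation_LCL`), and finally
#' applies the alias table. Case is preserved.
#'
#' @param label Character vector of raw labels.
#' @param aliases Named character vector; see [domain_aliases()].
#' @return Character vector of canonical tokens.
#' @examples
#' normalize_domain_label(c("PP-binding", "Condensation(LCL)", " PCP "))
#' @export
normalize_domain_label <- function(label, aliases = domain_aliases()) {
  x <- trimws(as.character(label))
  x <- gsub("\\(([^)]*)\\)", "_\\1", x)   # subtype parentheses
  x <- gsub("[[:space:]-]+", "_", x)
  x <- gsub("_+", "_", x)
  x <- gsub("^_|_$", "", x)
  hit <- match(x, names(aliases))
  x[!is.na(hit)] <- unname(aliases[hit[!is.na(hit)]])
  x
}

#' Canonical homology groups of modular biosynthetic domains
#'
#' The substitution classes that matter when aligning NRPS / modular PKS
#' architectures: condensation-domain subtypes are mutually homologous, the
#' three carrier-protein labels (peptidyl carrier PCP, acyl carrier ACP,
#' PP-binding) are mutually homologous, and the ketosynthase subtypes form a
#' family. Tokens outside any group are only homologous to themselves.
#'
#' @return Named list of character vectors of canonical tokens.
#' @export
bda_homology_groups <- function() {
  list(
    condensation = c("Cond_Starter", "Cond_DCL", "Cond_LCL", "Cond_Dual"),
    adenylation  = c("AMP_binding", "CAL"),
    carrier      = c("PCP", "ACP", "PP_bind"),
    ketosynthase = c("Hyb_KS", "Itr_KS", "Mod_KS", "Trans_AT_KS"),
    thioesterase = "TE"
  )
}
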