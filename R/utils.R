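ZERO_TOL <- 1e-12   # below LP precision: treat stoichiometric entries as zero
FLUX_TOL <- 1e-6    # smallest flux considered "carried" by a reaction

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_rgem <- function(msg, class) {
  stop(structure(class = c(class, "rgem_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

warn_rgem <- function(msg) warning(msg, call. = FALSE)

#' Derive the compartment code from a metabolite id suffix
#'
#' Metabolite ids are compartment-suffixed (`"o2s_c"`, `"h2o2_m"`), following
#' the subscript convention of biochemical reaction tables. The compartment is
#' the substring after the final underscore.
#'
#' @param met_ids character vector of metabolite ids.
#' @return character vector of compartment codes (`""` when no suffix).
#' @examples
#' compartment_of(c("o2s_c", "h2o2_m", "ascb-L_c"))
#' @export
compartment_of <- function(met_ids) {
  out <- sub("^.*_([a-z0-9]+)$", "\\1", met_ids)
  out[!grepl("_", met_ids)] <- ""
  out
}

#' Strip the compartment suffix from metabolite ids
#'
#' @param met_ids character vector of metabolite ids.
#' @return ids without their trailing `_<compartment>` suffix.
#' @export
strip_compartment <- function(met_ids) sub("_[a-z0-9]+$", "", met_ids)

# deterministic seed derivation that stays well inside 32-bit integer range
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}
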