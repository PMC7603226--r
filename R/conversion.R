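#' Volumetric chain presets
#'
#' The conversion from peptide concentration in the injected digest (ug/mL)
#' to matrix concentration (ug/g) passes through an ordered chain of
#' dimensionless volumetric factors. Two presets ship:
#'
#' * `"extraction_only"` - the 1:20 solid/liquid extraction ratio alone
#'   (factor 20).
#' * `"extraction_spe"` - extraction 1:20 followed by the C18-SPE
#'   concentration of a 1 mL digest aliquot into 100 uL (factor 0.1 when
#'   mapping digest concentration back to matrix basis); net factor 2.
#'
#' @param name Preset name.
#' @return Named numeric vector of ordered factors.
#' @export
chain_preset <- function(name = c("extraction_spe", "extraction_only")) {
  name <- match.arg(name)
  switch(name,
    extraction_only = c("extraction solid/liquid 1:20" = 20),
    extraction_spe = c("extraction solid/liquid 1:20" = 20,
                       "SPE concentration 1 mL -> 100 uL" = 0.1)
  )
}

#' Conversion context for a peptide marker
#'
#' Bundles every constant needed to convert a peptide concentration in the
#' tryptic digest into total protein of the allergenic ingredient per gram of
#' matrix: peptide and parent-protein average masses, the protein's relative
#' abundance within the ingredient's total protein, the volumetric chain, and
#' the peptide release stoichiometry (moles of peptide liberated per mole of
#' protein under complete tryptic release).
#'
#' @param mw_pep Average peptide mass (Da).
#' @param mw_prot Average parent-protein mass (Da).
#' @param rel_abundance Protein mass fraction within the ingredient's total
#'   protein, in (0, 1].
#' @param chain Named numeric vector of positive volumetric factors, or a
#'   preset name for [chain_preset()].
#' @param release_stoichiometry Integer >= 1; moles of the marker peptide per
#'   mole of protein (1 under the complete-release assumption with a unique
#'   tryptic site).
#' @param marker Optional marker code carried as provenance.
#' @return Object of class `conversion_context`.
#' @export
conversion_context <- function(mw_pep, mw_prot, rel_abundance,
                               chain = chain_preset("extraction_only"),
                               release_stoichiometry = 1L,
                               marker = NULL) {
  if (is.character(chain) && length(chain) == 1L) chain <- chain_preset(chain)
  stopifnot(is.numeric(mw_pep), length(mw_pep) == 1L,
            is.numeric(mw_prot), length(mw_prot) == 1L,
            is.numeric(rel_abundance), length(rel_abundance) == 1L)
  if (mw_pep <= 0 || mw_prot <= 0) stop("masses must be > 0", call. = FALSE)
  if (rel_abundance <= 0 || rel_abundance > 1) {
    stop("rel_abundance must lie in (0, 1]", call. = FALSE)
  }
  if (length(chain) < 1L || any(chain <= 0)) {
    stop("all volumetric chain factors must be > 0", call. = FALSE)
  }
  rs <- as.integer(release_stoichiometry)
  if (is.na(rs) || rs < 1L) {
    stop("release_stoichiometry must be an integer >= 1", call. = FALSE)
  }
  structure(list(marker = marker, mw_pep = mw_pep, mw_prot = mw_prot,
                 rel_abundance = rel_abundance, chain = chain,
                 release_stoichiometry = rs),
            class = "conversion_context")
}

#' @export
print.conversion_context <- function(x, ...) {
  cat("<conversion_context>",
      if (!is.null(x$marker)) paste0(" marker ", x$marker) else "", "\n",
      sprintf("  mw_pep %.2f Da, mw_prot %.0f Da, rel_abundance %.3f\n",
              x$mw_pep, x$mw_prot, x$rel_abundance),
      "  chain: ", paste(sprintf("%s (x%g)", names(x$chain), x$chain),
                         collapse = "; "), "\n",
      sprintf("  factor %.4g (ug/g per ug/mL)\n", conversion_factor(x)),
      sep = "")
  invisible(x)
}

#' Build a conversion context from the registry
#'
#' @param registry An `allergen_registry`.
#' @param code Marker code.
#' @param chain Volumetric chain or preset name; the two-step
#'   extraction + SPE preset is the default for registry-derived contexts.
#' @return A `conversion_context`.
#' @export
marker_context <- function(registry, code, chain = chain_preset("extraction_spe")) {
  m <- get_marker(registry, code)
  p <- get_protein(registry, m$protein)
  conversion_context(mw_pep = m$mw_avg, mw_prot = p$mw_avg,
                     rel_abundance = p$rel_abundance, chain = chain,
                     marker = code)
}

#' Dimensionless peptide-to-total-protein conversion factor
#'
#' The multiplier taking a digest peptide concentration (ug/mL) to total
#' allergenic-ingredient protein per gram of matrix (ug/g):
#' `mw_prot / (mw_pep * release_stoichiometry) / rel_abundance * prod(chain)`.
#'
#' @param ctx A `conversion_context`.
#' @return Single positive number (ug/g per ug/mL).
#' @export
conversion_factor <- function(ctx) {
  stopifnot(inherits(ctx, "conversion_context"))
  ctx$mw_prot / (ctx$mw_pep * ctx$release_stoichiometry) /
    ctx$rel_abundance * prod(ctx$chain)
}

#' Convert peptide concentration to total allergen protein in matrix
#'
#' Applies the molar conversion chain: peptide mass concentration to peptide
#' molarity (via the average peptide mass), to protein molarity (complete
#' release), to protein mass concentration (protein mass), to total-protein
#' concentration (relative abundance), and finally to matrix basis through
#' the volumetric factors.
#'
#' @param c_pep Peptide concentration(s) in the digest, ug/mL; must be >= 0.
#' @param ctx A `conversion_context`.
#' @return Total allergenic-ingredient protein, ug per g of matrix; linear in
#'   `c_pep`.
#' @examples
#' ctx <- conversion_context(1000, 20000, 0.5, chain = c(extraction = 20))
#' peptide_to_total_protein(0.1, ctx)  # 80 ug/g
#' @export
peptide_to_total_protein <- function(c_pep, ctx) {
  stopifnot(is.numeric(c_pep))
  if (any(c_pep < 0, na.rm = TRUE)) {
    stop("peptide concentration must be >= 0", call. = FALSE)
  }
  c_pep * conversion_factor(ctx)
}

resolve_fraction <- function(ingredient) {
  f <- if (is.numeric(ingredient) && length(ingredient) == 1L) {
    ingredient
  } else if (is.list(ingredient) || is.data.frame(ingredient)) {
    as.numeric(ingredient[["protein_fraction"]])
  } else {
    stop("ingredient must be a protein fraction or an ingredient record",
         call. = FALSE)
  }
  if (is.na(f) || f <= 0 || f > 1) {
    stop("protein_fraction must lie in (0, 1]", call. = FALSE)
  }
  f
}

#' Ingredient / total-protein unit conversions
#'
#' `ingredient_to_protein()` converts an allergenic-ingredient concentration
#' (ug ingredient per g matrix, equivalently mg/kg) into total protein of
#' that ingredient via its protein mass fraction;
#' `protein_to_ingredient()` is its exact inverse.
#'
#' @param c_ingredient,c_protein Concentration(s), ug/g (= mg/kg); >= 0.
#' @param ingredient Either a numeric protein fraction in (0, 1] or an
#'   ingredient record carrying `protein_fraction` (e.g. a row of
#'   `registry$ingredients` or the result of [marker_ingredient()]).
#' @return Converted concentration(s), ug/g.
#' @examples
#' ingredient_to_protein(10, 0.354)   # MoniQA low level: 3.54 ug protein/g
#' protein_to_ingredient(3.54, 0.354) # back to 10 ug ingredient/g
#' @export
ingredient_to_protein <- function(c_ingredient, ingredient) {
  stopifnot(is.numeric(c_ingredient))
  if (any(c_ingredient < 0, na.rm = TRUE)) {
    stop("ingredient concentration must be >= 0", call. = FALSE)
  }
  c_ingredient * resolve_fraction(ingredient)
}

#' @rdname ingredient_to_protein
#' @export
protein_to_ingredient <- function(c_protein, ingredient) {
  stopifnot(is.numeric(c_protein))
  if (any(c_protein < 0, na.rm = TRUE)) {
    stop("protein concentration must be >= 0", call. = FALSE)
  }
  c_protein / resolve_fraction(ingredient)
}
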