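#' Load an allergen marker registry
#'
#' Reads a YAML registry document describing allergenic ingredients, their
#' proteins, proteotypic peptide markers and MRM transitions, validates it,
#' and fills in any missing peptide masses from the sequence. The shipped
#' default covers milk (alpha-S1-casein: FFV, YLG; beta-lactoglobulin: TPE,
#' VLV) and egg (ovalbumin: ISQ, GGL; vitellogenin-2: NIP, NIG).
#'
#' @param path Path to a registry YAML file; defaults to the shipped registry.
#' @return An object of class `allergen_registry`: a list with data frames
#'   `ingredients` and `proteins`, a named list `markers`, and a `transitions`
#'   data frame (one row per transition).
#' @examples
#' reg <- load_registry()
#' reg$markers$FFV$mw_avg
#' @export
load_registry <- function(path = system.file("extdata", "registry.yaml",
                                             package = "allerquant")) {
  if (!file.exists(path)) stop("registry file not found: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  registry_from_list(doc, source = path)
}

#' @rdname load_registry
#' @export
default_registry <- function() load_registry()

registry_from_list <- function(doc, source = "<list>") {
  for (part in c("ingredients", "proteins", "markers")) {
    if (is.null(doc[[part]]) || length(doc[[part]]) == 0L) {
      stop("registry is missing section '", part, "'", call. = FALSE)
    }
  }

  ingredients <- do.call(rbind, lapply(doc$ingredients, function(x) {
    data.frame(name = x$name, allergen = x$allergen,
               protein_fraction = as.numeric(x$protein_fraction),
               stringsAsFactors = FALSE)
  }))
  if (any(ingredients$protein_fraction <= 0 | ingredients$protein_fraction > 1)) {
    stop("ingredient protein_fraction must lie in (0, 1]", call. = FALSE)
  }
  if (anyDuplicated(ingredients$name)) {
    stop("duplicate ingredient names in registry", call. = FALSE)
  }

  proteins <- do.call(rbind, lapply(doc$proteins, function(x) {
    data.frame(name = x$name, allergen = x$allergen,
               ingredient = x$ingredient,
               uniprot_hint = if (is.null(x$uniprot_hint)) NA_character_ else x$uniprot_hint,
               mw_avg = as.numeric(x$mw_avg),
               rel_abundance = as.numeric(x$rel_abundance),
               stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(proteins$name)) {
    stop("duplicate protein names in registry", call. = FALSE)
  }
  if (any(proteins$mw_avg <= 0)) stop("protein mw_avg must be > 0", call. = FALSE)
  if (any(proteins$rel_abundance <= 0 | proteins$rel_abundance > 1)) {
    stop("protein rel_abundance must lie in (0, 1]", call. = FALSE)
  }
  dangling_ing <- setdiff(proteins$ingredient, ingredients$name)
  if (length(dangling_ing) > 0L) {
    stop("protein references unknown ingredient: ",
         paste(dangling_ing, collapse = ", "), call. = FALSE)
  }

  codes <- vapply(doc$markers, function(x) x$code, character(1))
  if (anyDuplicated(codes)) {
    stop("duplicate marker codes in registry: ",
         paste(unique(codes[duplicated(codes)]), collapse = ", "), call. = FALSE)
  }

  markers <- lapply(doc$markers, function(x) {
    if (is.null(x$protein) || !x$protein %in% proteins$name) {
      stop("marker ", x$code, " references unknown protein '",
           if (is.null(x$protein)) "<missing>" else x$protein, "'", call. = FALSE)
    }
    if (is.null(x$transitions) || length(x$transitions) == 0L) {
      stop("marker ", x$code, " has no transitions", call. = FALSE)
    }
    trans <- do.call(rbind, lapply(x$transitions, function(tr) {
      role <- match.arg(tr$role, c("quantifier", "qualifier"))
      data.frame(q1_mz = as.numeric(tr$q1_mz), q3_mz = as.numeric(tr$q3_mz),
                 role = role,
                 collision_energy = if (is.null(tr$collision_energy)) NA_real_
                                    else as.numeric(tr$collision_energy),
                 stringsAsFactors = FALSE)
    }))
    if (any(trans$q1_mz <= 0) || any(trans$q3_mz <= 0)) {
      stop("marker ", x$code, ": transition m/z must be > 0", call. = FALSE)
    }
    nq <- sum(trans$role == "quantifier")
    if (nq != 1L) {
      stop("marker ", x$code, " must have exactly one quantifier transition (found ",
           nq, ")", call. = FALSE)
    }
    mw <- if (is.null(x$mw_avg)) peptide_average_mass(x$sequence)
          else as.numeric(x$mw_avg)
    if (mw <= 0) stop("marker ", x$code, ": mw_avg must be > 0", call. = FALSE)
    list(code = x$code, sequence = x$sequence, protein = x$protein,
         mw_avg = mw, transitions = trans)
  })
  names(markers) <- codes

  transitions <- do.call(rbind, lapply(markers, function(m) {
    cbind(data.frame(marker = m$code, sequence = m$sequence,
                     stringsAsFactors = FALSE), m$transitions)
  }))
  rownames(transitions) <- NULL

  structure(list(ingredients = ingredients, proteins = proteins,
                 markers = markers, transitions = transitions,
                 schema = if (is.null(doc$schema)) "allerquant-registry/1" else doc$schema,
                 source = source),
            class = "allergen_registry")
}

#' @export
print.allergen_registry <- function(x, ...) {
  cat("<allergen_registry> ", length(x$markers), " markers, ",
      nrow(x$proteins), " proteins, ",
      length(unique(x$ingredients$allergen)), " allergens\n", sep = "")
  for (m in x$markers) {
    q <- m$transitions[m$transitions$role == "quantifier", ]
    cat(sprintf("  %-4s %-18s %-18s %7.1f Da  quantifier %.1f>%.1f\n",
                m$code, m$sequence, m$protein, m$mw_avg, q$q1_mz, q$q3_mz))
  }
  invisible(x)
}

#' Serialize a registry back to its document form
#'
#' Inverse of [load_registry()]: produces a plain list that round-trips
#' through YAML to an identical registry.
#'
#' @param registry An `allergen_registry`.
#' @return A list mirroring the registry document schema.
#' @export
registry_to_list <- function(registry) {
  stopifnot(inherits(registry, "allergen_registry"))
  list(
    schema = registry$schema,
    ingredients = lapply(seq_len(nrow(registry$ingredients)), function(i) {
      as.list(registry$ingredients[i, , drop = FALSE])
    }),
    proteins = lapply(seq_len(nrow(registry$proteins)), function(i) {
      as.list(registry$proteins[i, , drop = FALSE])
    }),
    markers = lapply(registry$markers, function(m) {
      list(code = m$code, sequence = m$sequence, protein = m$protein,
           mw_avg = m$mw_avg,
           transitions = lapply(seq_len(nrow(m$transitions)), function(i) {
             tr <- as.list(m$transitions[i, , drop = FALSE])
             if (is.na(tr$collision_energy)) tr$collision_energy <- NULL
             tr
           }))
    })
  )
}

get_marker <- function(registry, code) {
  m <- registry$markers[[code]]
  if (is.null(m)) stop("unknown marker code '", code, "'", call. = FALSE)
  m
}

get_protein <- function(registry, name) {
  i <- match(name, registry$proteins$name)
  if (is.na(i)) stop("unknown protein '", name, "'", call. = FALSE)
  registry$proteins[i, , drop = FALSE]
}

get_ingredient <- function(registry, name) {
  i <- match(name, registry$ingredients$name)
  if (is.na(i)) stop("unknown ingredient '", name, "'", call. = FALSE)
  registry$ingredients[i, , drop = FALSE]
}

#' Ingredient backing a marker
#'
#' Resolves marker -> parent protein -> allergenic ingredient.
#'
#' @param registry An `allergen_registry`.
#' @param code Marker code (e.g. `"FFV"`).
#' @return One-row data frame from `registry$ingredients`.
#' @export
marker_ingredient <- function(registry, code) {
  m <- get_marker(registry, code)
  p <- get_protein(registry, m$protein)
  get_ingredient(registry, p$ingredient)
}

#' Allergen label for a marker
#' @inheritParams marker_ingredient
#' @return `"milk"` or `"egg"` for the default registry.
#' @export
marker_allergen <- function(registry, code) {
  get_protein(registry, get_marker(registry, code)$protein)$allergen
}

quantifier_transition <- function(registry, code) {
  tr <- get_marker(registry, code)$transitions
  tr[tr$role == "quantifier", , drop = FALSE]
}

qualifier_transitions <- function(registry, code) {
  tr <- get_marker(registry, code)$transitions
  tr[tr$role == "qualifier", , drop = FALSE]
}

transition_id <- function(q1, q3) sprintf("%.1f>%.1f", q1, q3)

#' Export the registry transition list
#'
#' Writes a transition-list CSV (one row per transition) in the conventional
#' targeted-proteomics layout.
#'
#' @param registry An `allergen_registry`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
export_transition_list <- function(registry, path) {
  out <- data.frame(
    peptide_sequence = registry$transitions$sequence,
    marker_code = registry$transitions$marker,
    q1_mz = registry$transitions$q1_mz,
    q3_mz = registry$transitions$q3_mz,
    role = registry$transitions$role,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
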