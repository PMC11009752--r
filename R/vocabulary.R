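## Drug and event vocabulary: verbatim drug names -> products -> ingredients,
## and preferred terms -> named event groups (SOC-like or SMQ-like sets).
## MedDRA itself is licensed, so term lists are user-supplied configuration;
## a small demo vocabulary covering the inhaled muscarinic-antagonist study
## design ships with the package (see pv_demo_vocabulary()).

#' Construct a drug/event vocabulary
#'
#' A vocabulary bundles a drug dictionary with a set of named event groups.
#' The drug dictionary maps verbatim (as-reported) drug names,
#' case-insensitively and after trimming, to product identifiers, and each
#' product to its non-empty set of ingredients — a singleton for a
#' monotherapy, two or three ingredients for a fixed-dose combination. Event
#' groups are flat, possibly overlapping sets of preferred terms, playing the
#' role of a system organ class or of a standardized query.
#'
#' @param drugs Named list: `product_id -> list(synonyms = chr, ingredients
#'   = chr, class = chr or NULL)`. The product id itself is always accepted
#'   as a synonym.
#' @param event_groups Named list: `group_id -> list(label = chr, terms =
#'   chr)`. Terms are stored uppercased and trimmed.
#' @param ingredient_classes Optional named character vector mapping
#'   ingredient ids to drug-class labels (e.g. LAMA, SAMA, LABA, ICS);
#'   single-ingredient products with a `class` field contribute to this map
#'   automatically.
#' @return An object of class `pv_vocabulary` with elements `synonym_map`
#'   (lowercased synonym -> product_id), `products` (product_id ->
#'   ingredient character vector), `class_map` and `event_groups`.
#' @seealso [read_vocabulary()], [normalize_drug()], [classify_event()]
#' @export
pv_vocabulary <- function(drugs, event_groups,
                          ingredient_classes = character()) {
  if (length(drugs) == 0) pv_abort("vocabulary needs at least one drug")
  if (is.null(names(drugs)) || any(!nzchar(names(drugs)))) {
    pv_abort("drugs must be a named list keyed by product_id")
  }
  products <- list()
  synonym_map <- character()
  class_map <- as.character(ingredient_classes)
  names(class_map) <- names(ingredient_classes)
  for (pid in names(drugs)) {
    d <- drugs[[pid]]
    ingredients <- unique(trimws(as.character(d$ingredients %||% pid)))
    if (length(ingredients) == 0 || any(!nzchar(ingredients))) {
      pv_abort(paste0("product '", pid, "' has an empty ingredient set"))
    }
    products[[pid]] <- ingredients
    syn <- unique(tolower(trimws(c(pid, as.character(d$synonyms)))))
    syn <- syn[nzchar(syn)]
    clash <- syn[syn %in% names(synonym_map) & synonym_map[syn] != pid]
    if (length(clash) > 0) {
      pv_abort(paste0("synonym(s) mapped to two products: ",
                      paste(clash, collapse = ", ")))
    }
    new_syn <- stats::setNames(rep(pid, length(syn)), syn)
    synonym_map <- c(synonym_map[!names(synonym_map) %in% syn], new_syn)
    if (!is.null(d$class) && length(ingredients) == 1 &&
        !ingredients %in% names(class_map)) {
      class_map[ingredients] <- as.character(d$class)
    }
  }
  groups <- list()
  for (gid in names(event_groups)) {
    g <- event_groups[[gid]]
    terms <- unique(normalize_pt(g$terms))
    terms <- terms[nzchar(terms) & !is.na(terms)]
    if (length(terms) == 0) {
      pv_abort(paste0("event group '", gid, "' has no terms"))
    }
    groups[[gid]] <- list(label = as.character(g$label %||% gid),
                          terms = terms)
  }
  structure(list(synonym_map = synonym_map, products = products,
                 class_map = class_map, event_groups = groups),
            class = "pv_vocabulary")
}

#' @export
print.pv_vocabulary <- function(x, ...) {
  cat(sprintf("<pv_vocabulary: %d product(s), %d synonym(s), %d event group(s)>\n",
              length(x$products), length(x$synonym_map),
              length(x$event_groups)))
  invisible(x)
}

#' Read a vocabulary from a YAML file
#'
#' The file has a `drugs` section (`product_id: {synonyms: [...],
#' ingredients: [...], class: ...}`), an `event_groups` section
#' (`group_id: {label: ..., terms: [...]}`) and an optional
#' `ingredient_classes` map.
#'
#' @param path Path to the YAML vocabulary file.
#' @return A [pv_vocabulary()].
#' @export
read_vocabulary <- function(path) {
  if (!file.exists(path)) pv_abort(paste0("no such file: ", path))
  doc <- yaml::read_yaml(path)
  if (is.null(doc$drugs) || is.null(doc$event_groups)) {
    pv_abort("vocabulary file needs 'drugs' and 'event_groups' sections",
             class = "pv_format_error")
  }
  pv_vocabulary(doc$drugs, doc$event_groups,
                ingredient_classes = unlist(doc$ingredient_classes %||%
                                              list()))
}

#' The bundled demo vocabulary
#'
#' Loads the small vocabulary shipped with the package: the four long-acting
#' muscarinic antagonists (aclidinium, glycopyrronium, tiotropium,
#' umeclidinium) with their generic-name synonyms, the short-acting
#' comparator ipratropium, the fixed-dose dual and triple combination
#' products, and four event groups — a cardiac-disorders group plus the
#' three narrower arrhythmia / cardiac-failure / ischaemic-heart-disease
#' queries. Term membership is illustrative, not a licensed MedDRA release.
#'
#' @return A [pv_vocabulary()].
#' @export
pv_demo_vocabulary <- function() {
  read_vocabulary(system.file("extdata", "lama_demo_vocabulary.yaml",
                              package = "pvsignal", mustWork = TRUE))
}

#' Normalize a verbatim drug name to a product id
#'
#' Case-insensitive exact match on the trimmed verbatim name. Vectorized;
#' unmatched names yield `NA` (a valid outcome — the caller decides whether
#' to drop the mention or treat it as "other drug").
#'
#' @param vocabulary A [pv_vocabulary()].
#' @param verbatim Character vector of as-reported drug names.
#' @return Character vector of product ids, `NA` where unmatched.
#' @export
normalize_drug <- function(vocabulary, verbatim) {
  unname(vocabulary$synonym_map[tolower(trimws(as.character(verbatim)))])
}

#' Classify a preferred term into event groups
#'
#' Returns the ids of every event group whose term set contains `pt`
#' (case-insensitive, exact after trimming). A term may belong to several
#' groups — the narrower queries are not assumed disjoint from the broad
#' group or from each other — and an unmatched term returns an empty vector.
#'
#' @param vocabulary A [pv_vocabulary()].
#' @param pt A single preferred-term string.
#' @return Character vector of group ids (possibly empty).
#' @export
classify_event <- function(vocabulary, pt) {
  stopifnot(length(pt) == 1)
  ptn <- normalize_pt(pt)
  hits <- vapply(vocabulary$event_groups,
                 function(g) ptn %in% g$terms, logical(1))
  names(vocabulary$event_groups)[hits]
}

# vectorized membership of many PTs in one group
pts_in_group <- function(vocabulary, pts, group_id) {
  pts %in% vocabulary$event_groups[[group_id]]$terms
}

#' Products a report is exposed to
#'
#' Normalizes the report's drug mentions whose role is in `roles` and
#' returns the distinct product ids. The default restricts exposure to
#' suspect (and role-unknown) mentions, the usual convention in
#' disproportionality analysis; pass all of [pv_drug_roles()] to include
#' concomitants.
#'
#' @param vocabulary A [pv_vocabulary()].
#' @param report One report: either a one-row slice of a report set's
#'   tibble, a list with a `drugs` element, or a bare drug-mention tibble
#'   with columns `verbatim_name` and `role`.
#' @param roles Character vector of roles that count as exposure.
#' @return Sorted character vector of product ids (possibly empty).
#' @export
exposure_products <- function(vocabulary, report,
                              roles = c("primary_suspect",
                                        "secondary_suspect", "unknown")) {
  drugs <- if (is.data.frame(report) && "verbatim_name" %in% names(report)) {
    report
  } else if (!is.null(report$drugs)) {
    d <- report$drugs
    if (is.list(d) && !is.data.frame(d)) d <- d[[1]]
    d
  } else {
    pv_abort("cannot find drug mentions in 'report'")
  }
  hits <- normalize_drug(vocabulary, drugs$verbatim_name)
  sort(unique(hits[!is.na(hits) & drugs$role %in% roles]))
}

#' List event-group ids in a vocabulary
#' @param vocabulary A [pv_vocabulary()].
#' @return Character vector of group ids.
#' @export
event_group_ids <- function(vocabulary) names(vocabulary$event_groups)
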