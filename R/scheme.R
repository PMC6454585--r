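#' Entity categories of admission-record corpora
#'
#' The five clinical entity categories used throughout the package
#' defaults: anatomical parts, symptom descriptions (bound to an
#' anatomical part), independent symptoms, drugs, and operations.
#'
#' @return Character vector of category names.
#' @export
#' @examples
#' default_entity_categories()
default_entity_categories <- function() {
  c("AnatomicalPart", "SymptomDescription", "IndependentSymptoms",
    "Drug", "Operation")
}

default_category_codes <- function(categories) {
  defaults <- c(
    AnatomicalPart = "ana", SymptomDescription = "sym",
    IndependentSymptoms = "ind", Drug = "dru", Operation = "ope"
  )
  codes <- unname(defaults[categories])
  miss <- is.na(codes)
  codes[miss] <- tolower(substr(categories[miss], 1L, 3L))
  make.unique(codes, sep = "")
}

#' Construct a BIO label scheme
#'
#' A label scheme fixes the ordered label alphabet `{O} U {B_c, I_c}` for
#' a set of entity categories, together with bijective maps between
#' labels, indices, and categories. Label indices are 1-based with `"O"`
#' at index 1; the label count is `2 * length(categories) + 1`.
#'
#' @param categories Ordered character vector of entity category names.
#' @param codes Short codes used in the label strings (`B_<code>`,
#'   `I_<code>`); derived from the category names when `NULL`.
#' @return An object of class `label_scheme`: a list with elements
#'   `categories`, `codes`, `labels`, and `n` (number of labels).
#' @export
#' @examples
#' sch <- label_scheme(c("Drug", "Operation"))
#' sch$labels
label_scheme <- function(categories = default_entity_categories(),
                         codes = NULL) {
  if (length(categories) < 1L || anyDuplicated(categories) > 0L) {
    abort("`categories` must be a non-empty vector of unique names.")
  }
  codes <- codes %||% default_category_codes(categories)
  if (length(codes) != length(categories) || anyDuplicated(codes) > 0L) {
    abort("`codes` must be unique and match `categories` in length.")
  }
  labels <- c("O", as.vector(rbind(paste0("B_", codes), paste0("I_", codes))))
  structure(
    list(categories = categories, codes = codes, labels = labels,
         n = length(labels)),
    class = "label_scheme"
  )
}

#' @export
print.label_scheme <- function(x, ...) {
  cat("<label_scheme> ", x$n, " labels over ", length(x$categories),
      " categories\n", sep = "")
  cat("  ", paste(x$labels, collapse = " "), "\n", sep = "")
  invisible(x)
}

# label string -> 1-based index; unknown labels are an error
label_index <- function(scheme, labels) {
  idx <- match(labels, scheme$labels)
  if (anyNA(idx)) {
    bad <- unique(labels[is.na(idx)])
    abort(paste0("Unknown label(s): ", paste(bad, collapse = ", ")))
  }
  idx
}

# label string -> category name ("O" -> NA) and B/I role
label_category <- function(scheme, labels) {
  label_index(scheme, labels) # validates
  code <- sub("^[BI]_", "", labels)
  out <- scheme$categories[match(code, scheme$codes)]
  out[labels == "O"] <- NA_character_
  out
}
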