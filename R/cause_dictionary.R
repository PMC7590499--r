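#' Study groups
#'
#' The five mortality strata used throughout the package. Every death record
#' belongs to exactly one group, and each group carries its own closed list of
#' broad cause-of-death categories (see [default_cause_dictionary()]).
#'
#' @return Character vector of the five group codes, in canonical order:
#'   `"stillbirth"`, `"neonate"`, `"child"`, `"maternal"`, `"other_adult"`.
#' @export
#' @examples
#' va_groups()
va_groups <- function() {
  c("stillbirth", "neonate", "child", "maternal", "other_adult")
}

#' Reserved code for the residual cause category
#' @return The string `"non_conclusive"`.
#' @export
nonconclusive_code <- function() "non_conclusive"

#' Construct and validate a cause dictionary
#'
#' A cause dictionary is the closed list of broad cause-of-death categories,
#' each with a short machine code, a human-readable label, and the set of
#' study groups in which the cause is reportable. The reserved residual
#' category `"non_conclusive"` must be present exactly once and is always kept
#' last; it is in scope for every group.
#'
#' @param code character vector of unique short cause codes.
#' @param label character vector of display labels, same length as `code`.
#' @param groups character vector, same length as `code`; each element a
#'   semicolon-separated list of group codes (see [va_groups()]) in which the
#'   cause is reportable, or `"all"`.
#' @return A `data.frame` with class `cause_dictionary` and columns `code`,
#'   `label`, `groups`.
#' @export
cause_dictionary <- function(code, label, groups) {
  stopifnot(is.character(code), is.character(label), is.character(groups),
            length(code) == length(label), length(code) == length(groups))
  if (anyDuplicated(code)) {
    stop("cause codes must be unique: ", paste(code[duplicated(code)], collapse = ", "))
  }
  nc <- nonconclusive_code()
  if (sum(code == nc) != 1L) {
    stop("the dictionary must contain the reserved category '", nc, "' exactly once")
  }
  groups[groups == "all"] <- paste(va_groups(), collapse = ";")
  parsed <- strsplit(groups, ";", fixed = TRUE)
  bad <- !vapply(parsed, function(g) all(g %in% va_groups()), logical(1))
  if (any(bad)) {
    stop("unknown study group(s) in dictionary rows: ", paste(code[bad], collapse = ", "))
  }
  ord <- c(which(code != nc), which(code == nc))  # non-conclusive last
  d <- data.frame(code = code[ord], label = label[ord], groups = groups[ord],
                  stringsAsFactors = FALSE)
  # non-conclusive is always in scope everywhere
  d$groups[d$code == nc] <- paste(va_groups(), collapse = ";")
  for (g in va_groups()) {
    k <- length(group_causes_impl(d, g))
    if (k > 1L && k < 2L) stop("group '", g, "' has fewer than 2 causes")
  }
  class(d) <- c("cause_dictionary", "data.frame")
  d
}

group_causes_impl <- function(dictionary, group, substantive = FALSE) {
  parsed <- strsplit(dictionary$groups, ";", fixed = TRUE)
  keep <- vapply(parsed, function(g) group %in% g, logical(1))
  codes <- dictionary$code[keep]
  if (substantive) codes <- setdiff(codes, nonconclusive_code())
  codes
}

#' Causes reportable in a study group
#'
#' @param dictionary a [cause_dictionary()].
#' @param group one of [va_groups()].
#' @param substantive if `TRUE`, drop the residual `"non_conclusive"`
#'   category and return actual causes only.
#' @return Character vector of cause codes, dictionary order, residual last.
#' @export
group_causes <- function(dictionary, group, substantive = FALSE) {
  stopifnot(inherits(dictionary, "cause_dictionary"))
  group <- match.arg(group, va_groups())
  group_causes_impl(dictionary, group, substantive)
}

#' Default broad-category cause dictionary
#'
#' Broad cause-of-death categories for a hospital autopsy validation series:
#' 6 categories for stillbirths, 6 for neonates, 5 for children, 7 for
#' maternal deaths and 4 for other adults, each list ending in the residual
#' `"non_conclusive"` category. Categories such as "Infections" are shared
#' across groups under a single code.
#'
#' @return A [cause_dictionary()].
#' @export
#' @examples
#' d <- default_cause_dictionary()
#' group_causes(d, "maternal")
default_cause_dictionary <- function() {
  cause_dictionary(
    code = c("infections", "fetal_growth_restriction", "intrapartum_hypoxia",
             "intrauterine_hypoxia", "congenital_malformations",
             "preterm_complications", "intrapartum_complications",
             "other_diseases", "malignant_neoplasms", "abortion", "eclampsia",
             "obstetric_hemorrhage", "other_obstetric_complications",
             "non_obstetric_diseases", "non_conclusive"),
    label = c("Infections", "Fetal growth restriction", "Intrapartum hypoxia",
              "Intrauterine hypoxia", "Congenital malformations",
              "Preterm complications", "Intrapartum complication",
              "Other diseases", "Malignant neoplasms", "Abortion", "Eclampsia",
              "Obstetric hemorrhage", "Other obstetric complications",
              "Non-obstetric diseases", "Non-conclusive"),
    groups = c("all",
               "stillbirth", "stillbirth", "stillbirth",
               "stillbirth;neonate;child",
               "neonate", "neonate",
               "neonate;child;other_adult",
               "child;other_adult",
               "maternal", "maternal", "maternal", "maternal", "maternal",
               "all")
  )
}

#' Infection-level cause dictionary
#'
#' Subcategories used when re-analysing the subset of deaths whose
#' gold-standard broad category is infectious, pooled across study groups.
#'
#' @return A [cause_dictionary()] with 8 infection categories plus the
#'   residual category.
#' @export
infection_dictionary <- function() {
  cause_dictionary(
    code = c("disseminated_infections", "pneumonia", "meningitis",
             "tuberculosis", "diarrhoea", "hiv_aids_related", "malaria",
             "other_infections", "non_conclusive"),
    label = c("Disseminated infections", "Pneumonia", "Meningitis",
              "Tuberculosis", "Diarrhoea", "HIV/AIDS related", "Malaria",
              "Other infections", "Non-conclusive"),
    groups = rep("all", 9)
  )
}

#' Read / write a cause dictionary CSV
#'
#' The file has columns `code`, `label`, `groups` (semicolon-separated group
#' list or `"all"`).
#'
#' @param path file path.
#' @return `read_cause_dictionary()` returns a [cause_dictionary()];
#'   `write_cause_dictionary()` returns `path` invisibly.
#' @export
read_cause_dictionary <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("code", "label", "groups")
  if (!all(need %in% names(d))) {
    stop("dictionary file must have columns: ", paste(need, collapse = ", "))
  }
  cause_dictionary(d$code, d$label, d$groups)
}

#' @rdname read_cause_dictionary
#' @param dictionary a [cause_dictionary()].
#' @export
write_cause_dictionary <- function(dictionary, path) {
  stopifnot(inherits(dictionary, "cause_dictionary"))
  utils::write.csv(as.data.frame(dictionary), path, row.names = FALSE)
  invisible(path)
}

#' Map an ICD-10 code to a broad cause category
#'
#' Uses longest-prefix matching restricted to rows whose group is either the
#' record's study group or `"any"`. An unmatched code is an error, never a
#' silent assignment to the residual category.
#'
#' @param code an ICD-10 code string, e.g. `"O15.0"`.
#' @param group one of [va_groups()].
#' @param map a data.frame with columns `prefix`, `group`, `category`
#'   (see [read_icd10_map()]).
#' @return The mapped cause code (length-1 character).
#' @export
#' @examples
#' m <- data.frame(prefix = c("O15", "A4", "A41"),
#'                 group = c("maternal", "any", "neonate"),
#'                 category = c("eclampsia", "infections", "infections"))
#' map_icd10("O15.0", "maternal", m)
map_icd10 <- function(code, group, map) {
  stopifnot(is.character(code), length(code) == 1L, nzchar(code))
  group <- match.arg(group, va_groups())
  stopifnot(all(c("prefix", "group", "category") %in% names(map)))
  eligible <- map[map$group %in% c(group, "any"), , drop = FALSE]
  hits <- eligible[startsWith(code, eligible$prefix), , drop = FALSE]
  if (nrow(hits) == 0L) {
    stop("unmapped ICD-10 code '", code, "' for group '", group, "'")
  }
  best <- max(nchar(hits$prefix))
  hits <- hits[nchar(hits$prefix) == best, , drop = FALSE]
  # within equal prefix length, a group-specific row beats an "any" row
  if (nrow(hits) > 1L && any(hits$group == group)) {
    hits <- hits[hits$group == group, , drop = FALSE]
  }
  cats <- unique(hits$category)
  if (length(cats) > 1L) {
    stop("ambiguous ICD-10 mapping for '", code, "': ", paste(cats, collapse = ", "))
  }
  cats
}

#' Read the ICD-10 prefix map
#'
#' @param path CSV with columns `prefix`, `group` (a group code or `"any"`),
#'   `category`. If omitted, the illustrative map shipped with the package is
#'   loaded; the authoritative code-to-category table of any given study is
#'   configuration the user supplies.
#' @param dictionary optional [cause_dictionary()]; if given, every mapped
#'   category is checked against it.
#' @return A data.frame with columns `prefix`, `group`, `category`.
#' @export
read_icd10_map <- function(path = NULL, dictionary = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "icd10_map.csv", package = "vacheck",
                        mustWork = TRUE)
  }
  m <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("prefix", "group", "category")
  if (!all(need %in% names(m))) {
    stop("ICD-10 map must have columns: ", paste(need, collapse = ", "))
  }
  bad <- !(m$group %in% c(va_groups(), "any"))
  if (any(bad)) stop("unknown group(s) in ICD-10 map: ", paste(unique(m$group[bad]), collapse = ", "))
  if (!is.null(dictionary)) {
    missing <- setdiff(unique(m$category), dictionary$code)
    if (length(missing)) {
      stop("ICD-10 map categories absent from dictionary: ", paste(missing, collapse = ", "))
    }
  }
  m
}
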