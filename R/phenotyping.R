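# Marker booleans -> named phenotypes. Unlisted markers are "don't care",
# so one rule set serves human (HLA-A) and mouse (H-2Db) panels via channel
# renaming.

#' Define a phenotype rule
#'
#' A cell satisfies the rule when every channel in `require_pos` is
#' positive and every channel in `require_neg` is negative; channels not
#' listed do not constrain membership.
#'
#' @param name Unique phenotype label.
#' @param require_pos,require_neg Character vectors of channel names; must
#'   be disjoint.
#' @return An object of class `phenotype_rule`.
#' @export
phenotype_rule <- function(name, require_pos = character(),
                           require_neg = character()) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("`name` must be a non-empty string", call. = FALSE)
  }
  if (length(intersect(require_pos, require_neg)) > 0) {
    stop("rule '", name, "': require_pos and require_neg overlap",
         call. = FALSE)
  }
  structure(list(name = name,
                 require_pos = as.character(require_pos),
                 require_neg = as.character(require_neg)),
            class = "phenotype_rule")
}

#' Default phenotype rule set
#'
#' The compound phenotypes used by the figure-level statistics: PanCK+
#' tumor cells split by PGRN and MHCI status, and CD8 T cells with or
#' without the GzmB cytotoxicity gate.
#'
#' @return A named list of [phenotype_rule()]s.
#' @export
default_phenotype_rules <- function() {
  rules <- list(
    phenotype_rule("tumor", require_pos = "PanCK"),
    phenotype_rule("tumor_pgrn_pos", require_pos = c("PanCK", "PGRN")),
    phenotype_rule("tumor_pgrn_neg", require_pos = "PanCK",
                   require_neg = "PGRN"),
    phenotype_rule("tumor_pgrn_neg_mhc_pos",
                   require_pos = c("PanCK", "MHCI"), require_neg = "PGRN"),
    phenotype_rule("tumor_pgrn_pos_mhc_neg",
                   require_pos = c("PanCK", "PGRN"), require_neg = "MHCI"),
    phenotype_rule("cd8", require_pos = "CD8"),
    phenotype_rule("cd8_gzmb", require_pos = c("CD8", "GzmB"))
  )
  stats::setNames(rules, vapply(rules, `[[`, "", "name"))
}

#' Read phenotype rules from YAML
#'
#' The YAML is a list of entries with fields `name`, `require_pos`,
#' `require_neg`.
#'
#' @param path YAML file path.
#' @return A named list of [phenotype_rule()]s.
#' @export
read_phenotype_rules <- function(path) {
  raw <- yaml::read_yaml(path)
  rules <- lapply(raw, function(r) {
    phenotype_rule(r$name,
                   require_pos = unlist(r$require_pos) %||% character(),
                   require_neg = unlist(r$require_neg) %||% character())
  })
  stats::setNames(rules, vapply(rules, `[[`, "", "name"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify cells into phenotypes
#'
#' Adds one logical column per rule; a cell may satisfy several rules or
#' none. Re-classifying overwrites the phenotype columns, so the operation
#' is idempotent, and marker flags are never modified.
#'
#' @param cells A [cell_table()] carrying every channel the rules
#'   reference.
#' @param rules A list of [phenotype_rule()]s (default
#'   [default_phenotype_rules()]).
#' @return The cell table with phenotype columns and an updated
#'   `phenotypes` attribute.
#' @export
classify_cells <- function(cells, rules = default_phenotype_rules()) {
  nms <- vapply(rules, `[[`, "", "name")
  if (anyDuplicated(nms)) {
    stop("duplicate phenotype names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  channels <- attr(cells, "channels")
  for (r in rules) {
    unknown <- setdiff(c(r$require_pos, r$require_neg), channels)
    if (length(unknown) > 0) {
      stop("rule '", r$name, "' references unknown channel(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  n <- nrow(cells)
  for (r in rules) {
    member <- rep(TRUE, n)
    for (ch in r$require_pos) member <- member & as.logical(cells[[ch]])
    for (ch in r$require_neg) member <- member & !as.logical(cells[[ch]])
    cells[[r$name]] <- member
  }
  attr(cells, "phenotypes") <- unname(nms)
  keep_cell_attrs(cells, cells)
}
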