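#' The 74-structure brain atlas catalogue
#'
#' The analysis quantifies perfusion over 74 cortical and subcortical
#' structures following the Oishi-style whole-brain parcellation: 36
#' left/right structure pairs plus two midline brainstem structures (pons and
#' medulla). The catalogue records, for each structure, its integer label id,
#' name, hemisphere, laterality partner and cortical/subcortical class; the
#' geometry of the parcellation is not part of the catalogue.
#'
#' @section File format:
#' A catalogue is a tab-separated file with header
#' `id  name  hemisphere  partner_id  class` where `hemisphere` is one of
#' `left`, `right`, `midline`, `partner_id` points at the contralateral
#' homologue (a midline structure is its own partner) and `class` is
#' `cortical` or `subcortical`. The default catalogue ships with the package
#' (`system.file("extdata", "atlas74.tsv", package = "sudepspect")`).
#'
#' @param path Path to a catalogue TSV. Defaults to the bundled catalogue.
#' @return An object of class `atlas_spec`: a data frame with columns
#'   `id`, `name`, `hemisphere`, `partner_id`, `class` and exactly 74 rows.
#' @examples
#' atlas <- load_atlas_spec()
#' nrow(atlas)          # 74
#' table(atlas$class)
#' @export
load_atlas_spec <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "atlas74.tsv", package = "sudepspect")
  }
  if (!file.exists(path)) abort("atlas catalogue not found: %s", path)
  df <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE),
    error = function(e) abort("failed to parse atlas catalogue '%s': %s",
                              path, conditionMessage(e)))
  required <- c("id", "name", "hemisphere", "partner_id", "class")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort("atlas catalogue is missing column(s): %s",
          paste(missing, collapse = ", "))
  }
  df <- df[required]
  df$id <- as.integer(df$id)
  df$partner_id <- as.integer(df$partner_id)
  validate_atlas_spec(df)
  class(df) <- c("atlas_spec", "data.frame")
  df
}

#' Validate an atlas catalogue data frame
#'
#' Checks the structural invariants of the catalogue: 74 rows, unique positive
#' ids, unique names, a hemisphere/partner relation that is an involution
#' (left partners right and vice versa; midline structures partner
#' themselves), and a cortical/subcortical class on every row.
#'
#' @param df Data frame with catalogue columns.
#' @return Invisibly `TRUE`; errors name the offending row otherwise.
#' @keywords internal
validate_atlas_spec <- function(df) {
  if (nrow(df) != 74L) {
    abort("atlas catalogue must have exactly 74 structures, found %d", nrow(df))
  }
  if (anyNA(df$id) || any(df$id < 1L)) abort("atlas ids must be integers >= 1")
  if (anyDuplicated(df$id)) {
    abort("duplicate atlas id: %d", df$id[anyDuplicated(df$id)])
  }
  if (anyDuplicated(df$name)) {
    abort("duplicate atlas structure name: '%s'",
          df$name[anyDuplicated(df$name)])
  }
  bad <- !df$hemisphere %in% c("left", "right", "midline")
  if (any(bad)) {
    abort("row id %d: unknown hemisphere '%s'",
          df$id[which(bad)[1]], df$hemisphere[which(bad)[1]])
  }
  bad <- !df$class %in% c("cortical", "subcortical")
  if (any(bad)) {
    abort("row id %d: unknown class '%s'",
          df$id[which(bad)[1]], df$class[which(bad)[1]])
  }
  idx <- match(df$partner_id, df$id)
  if (anyNA(idx)) {
    abort("row id %d: partner_id %d does not exist",
          df$id[which(is.na(idx))[1]], df$partner_id[which(is.na(idx))[1]])
  }
  # partner relation must be an involution
  back <- df$partner_id[idx]
  bad <- back != df$id
  if (any(bad)) {
    i <- which(bad)[1]
    abort("partner relation is not an involution at row id %d ('%s'): %d -> %d -> %d",
          df$id[i], df$name[i], df$id[i], df$partner_id[i], back[i])
  }
  # midline iff self-partnered; left must partner right
  self <- df$partner_id == df$id
  if (any(self & df$hemisphere != "midline")) {
    i <- which(self & df$hemisphere != "midline")[1]
    abort("row id %d ('%s') partners itself but is not midline", df$id[i], df$name[i])
  }
  if (any(!self & df$hemisphere == "midline")) {
    i <- which(!self & df$hemisphere == "midline")[1]
    abort("midline row id %d ('%s') must be its own partner", df$id[i], df$name[i])
  }
  cross <- df$hemisphere[idx]
  bad <- (df$hemisphere == "left" & cross != "right") |
         (df$hemisphere == "right" & cross != "left")
  if (any(bad)) {
    i <- which(bad)[1]
    abort("row id %d ('%s'): %s structure must partner the opposite hemisphere",
          df$id[i], df$name[i], df$hemisphere[i])
  }
  invisible(TRUE)
}

#' Strip a laterality suffix from structure names
#'
#' Maps `putamen_L`, `putamen_R`, `putamen_ipsi`, `putamen_contra` to
#' `putamen`; names with no suffix (midline) pass through.
#'
#' @param x Character vector of structure names.
#' @return Character vector of base names.
#' @export
structure_base_name <- function(x) {
  sub("_(L|R|ipsi|contra)$", "", x)
}

#' Look up cortical/subcortical class for structure names
#'
#' Accepts raw catalogue names (`_L`/`_R` suffixes), seizure-onset-relative
#' names (`_ipsi`/`_contra`) or midline names, resolving through the base name.
#'
#' @param names Character vector of structure names.
#' @param atlas An `atlas_spec`.
#' @return Character vector of classes (`cortical`/`subcortical`).
#' @export
structure_class <- function(names, atlas) {
  base <- structure_base_name(names)
  key <- structure_base_name(atlas$name)
  cls <- atlas$class[!duplicated(key)]
  names(cls) <- key[!duplicated(key)]
  out <- unname(cls[base])
  if (anyNA(out)) {
    abort("structure name(s) not in atlas: %s",
          paste(unique(names[is.na(out)]), collapse = ", "))
  }
  out
}

#' Re-key a ROI activity table to the seizure-onset-relative convention
#'
#' Seizure onset side differs between patients, so cross-patient comparison
#' uses an ipsilateral/contralateral convention: structures in the hemisphere
#' of seizure onset become `*_ipsi`, their partners `*_contra`, and midline
#' structures keep their names. This is the table-level equivalent of flipping
#' the co-registered scans left-right for left-onset patients: activity values
#' are permuted between homologous rows, never altered.
#'
#' A table already in ipsi/contra naming is returned unchanged, so the
#' operation is idempotent for a fixed onset side.
#'
#' @param table A ROI activity table (data frame with a `structure` column of
#'   catalogue names, plus any value columns).
#' @param onset_side `"left"` or `"right"`: hemisphere of the seizure onset
#'   zone.
#' @param atlas An `atlas_spec`.
#' @return The table with `structure` re-keyed to `*_ipsi` / `*_contra` /
#'   midline names. Row order follows the input.
#' @examples
#' atlas <- load_atlas_spec()
#' tab <- data.frame(structure = c("putamen_L", "putamen_R", "medulla"),
#'                   mean_counts = c(80, 120, 60))
#' relabel_ipsilateral(tab, "right", atlas)$structure
#' @export
relabel_ipsilateral <- function(table, onset_side, atlas) {
  if (!onset_side %in% c("left", "right")) {
    abort("unknown onset side '%s' (must be 'left' or 'right')", onset_side)
  }
  if (!"structure" %in% names(table)) abort("table has no 'structure' column")
  s <- table$structure
  if (all(grepl("_(ipsi|contra)$", s) | s %in% atlas$name[atlas$hemisphere == "midline"])) {
    return(table)  # already relabeled: idempotent
  }
  unknown <- setdiff(s, atlas$name)
  if (length(unknown)) {
    abort("structure name(s) not in atlas: %s", paste(unknown, collapse = ", "))
  }
  hemi <- atlas$hemisphere[match(s, atlas$name)]
  base <- structure_base_name(s)
  new <- s
  ipsi_hemi <- onset_side
  new[hemi == ipsi_hemi] <- paste0(base[hemi == ipsi_hemi], "_ipsi")
  new[hemi %in% c("left", "right") & hemi != ipsi_hemi] <-
    paste0(base[hemi %in% c("left", "right") & hemi != ipsi_hemi], "_contra")
  table$structure <- new
  table
}

#' Map seizure-onset-relative names back to catalogue names
#'
#' Inverse of [relabel_ipsilateral()] for a known onset side: `*_ipsi` maps to
#' the onset-side hemisphere, `*_contra` to the other.
#'
#' @param names Character vector of `*_ipsi` / `*_contra` / midline names.
#' @param onset_side `"left"` or `"right"`.
#' @return Character vector of catalogue (`_L`/`_R`/midline) names.
#' @export
resolve_lateral_names <- function(names, onset_side) {
  if (!onset_side %in% c("left", "right")) {
    abort("unknown onset side '%s' (must be 'left' or 'right')", onset_side)
  }
  ipsi <- if (onset_side == "left") "_L" else "_R"
  contra <- if (onset_side == "left") "_R" else "_L"
  out <- sub("_ipsi$", ipsi, names)
  sub("_contra$", contra, out)
}
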