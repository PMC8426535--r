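#' Load a label hierarchy
#'
#' The label layout shared by the score matrix, losses and predictions: up
#' to 10 organelles (columns), each with up to 8 suborganelle slots (rows).
#' Empty slots carry zero targets.  The bundled default covers the 10 major
#' eukaryotic compartments with 44 occupied suborganelle cells.
#'
#' @param path Path to a TSV with columns `organelle, suborganelle, slot`,
#'   or `"BUILTIN"` / `NULL` for the bundled default.
#' @return A `loc_hierarchy`: list with `organelles` (ordered character),
#'   `slots` (8 x n character matrix, `NA` = empty), `cells` (tibble
#'   `suborganelle, row, col, organelle`), `n_class`.
#' @export
load_hierarchy <- function(path = NULL) {
  if (is.null(path) || identical(path, "BUILTIN")) path <- .extdata("hierarchy_uniloc.tsv")
  tab <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  hierarchy(split(tab$suborganelle, factor(tab$organelle, levels = unique(tab$organelle))))
}

#' Build a label hierarchy from a named list
#'
#' @param spec Named list: organelle name -> character vector of
#'   suborganelle names (may be empty).  At most 10 organelles with at most
#'   8 suborganelles each.
#' @return A `loc_hierarchy` object.
#' @export
hierarchy <- function(spec) {
  orgs <- names(spec)
  if (is.null(orgs) || any(!nzchar(orgs))) .stopf("every organelle needs a name")
  if (length(orgs) > 10) .stopf("at most 10 organelles supported, got %d", length(orgs))
  if (anyDuplicated(orgs)) .stopf("duplicate organelle name")
  n_sub <- vapply(spec, length, 1L)
  if (any(n_sub > 8))
    .stopf("organelle '%s' has %d suborganelles; at most 8 slots exist",
           orgs[which.max(n_sub)], max(n_sub))
  subs <- unlist(spec, use.names = FALSE)
  if (anyDuplicated(subs))
    .stopf("duplicate suborganelle name '%s'", subs[duplicated(subs)][1])

  slots <- matrix(NA_character_, nrow = 8, ncol = length(orgs),
                  dimnames = list(NULL, orgs))
  for (j in seq_along(orgs)) {
    s <- spec[[j]]
    if (length(s) > 0) slots[seq_along(s), j] <- s
  }
  cells <- tibble(
    suborganelle = subs,
    row = unlist(lapply(n_sub, seq_len), use.names = FALSE),
    col = rep(seq_along(orgs), n_sub),
    organelle = rep(orgs, n_sub)
  )
  structure(list(organelles = orgs, slots = slots, cells = cells,
                 n_class = nrow(cells)),
            class = "loc_hierarchy")
}

#' @export
print.loc_hierarchy <- function(x, ...) {
  cat(sprintf("<loc_hierarchy> %d organelles, %d suborganelle classes\n",
              length(x$organelles), x$n_class))
  invisible(x)
}

#' Convert record labels to network targets
#'
#' Occupied cells named among the record's suborganelle labels get target 1;
#' all other cells, including empty slots, get 0.  The organelle target is 1
#' for any organelle that is annotated directly or through one of its
#' suborganelles.  Records carrying only organelle-level labels are flagged
#' `lv1_only`: their cell matrix is all-zero and only the organelle vector
#' is meaningful.
#'
#' @param organelles,suborganelles Character vectors of labels (a one-row
#'   record tibble may be passed as `organelles`, in which case both label
#'   sets are taken from it).
#' @param h A `loc_hierarchy`.
#' @return List with `matrix` (8 x n 0/1), `org` (0/1 vector over
#'   organelles), `lv1_only` flag.
#' @export
labels_to_matrix <- function(organelles, suborganelles = NULL, h) {
  if (is.data.frame(organelles)) {
    suborganelles <- organelles$suborganelles[[1]]
    organelles <- organelles$organelles[[1]]
  }
  unknown <- setdiff(suborganelles, h$cells$suborganelle)
  if (length(unknown) > 0) .stopf("unknown suborganelle label '%s'", unknown[1])
  unknown <- setdiff(organelles, h$organelles)
  if (length(unknown) > 0) .stopf("unknown organelle label '%s'", unknown[1])

  m <- matrix(0, nrow = 8, ncol = length(h$organelles),
              dimnames = list(NULL, h$organelles))
  idx <- h$cells[h$cells$suborganelle %in% suborganelles, ]
  m[cbind(idx$row, idx$col)] <- 1
  org <- as.numeric(h$organelles %in% union(organelles, idx$organelle))
  names(org) <- h$organelles
  list(matrix = m, org = org,
       lv1_only = length(suborganelles) == 0 && length(organelles) > 0)
}

#' Recover the suborganelle label set from a target matrix
#'
#' @param m 8 x n 0/1 matrix in the layout of `h`.
#' @param h A `loc_hierarchy`.
#' @return Character vector of suborganelle names whose cells are 1.
#' @export
matrix_to_labels <- function(m, h) {
  occ <- h$cells
  occ$suborganelle[m[cbind(occ$row, occ$col)] > 0]
}

#' Look up the matrix cell of a suborganelle
#' @param name Suborganelle name.
#' @param h A `loc_hierarchy`.
#' @return Named integer vector `c(row =, col =)`.
#' @export
cell_of <- function(name, h) {
  i <- match(name, h$cells$suborganelle)
  if (is.na(i)) .stopf("unknown suborganelle label '%s'", name)
  c(row = h$cells$row[i], col = h$cells$col[i])
}
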