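# Myocardial jeopardy indices from a scored coronary branch tree.
#
# Each branch carries a size score 0-3 from its base-to-apex extent; the
# myocardial jeopardy index (MJI) is the score distal to the lesion as a
# proportion of the total score of all branches, a proxy for the fraction
# of myocardium subtended by the lesion.

#' Scored coronary tree
#'
#' @param branches data.frame with columns `id`, `parent` (`NA` for a
#'   territory root), `vessel` (free-text name, used only for Duke segment
#'   mapping), `extent` (fraction of the base-to-apex distance the branch
#'   covers, in `[0, 1]`), and `significant` (logical; an insignificant
#'   vessel scores 0 regardless of extent).
#' @param lesion_branch id of the branch carrying the lesion under study.
#' @param lesion_offset `"proximal"`, `"mid"` or `"distal"` position marker
#'   on that branch. The branch's own score counts fully toward the distal
#'   territory at any offset (no partial-branch proration), so the marker
#'   is descriptive metadata; it is validated and retained.
#' @return an object of class `coronary_tree`.
#' @examples
#' tr <- coronary_tree(data.frame(
#'   id = c("LAD", "Dx", "LCx", "OM", "RCA"),
#'   parent = c(NA, "LAD", NA, "LCx", NA),
#'   vessel = c("LAD", "diagonal", "LCx", "OM", "RCA"),
#'   extent = c(0.8, 0.2, 0.5, 0.3, 0.9),
#'   significant = TRUE), lesion_branch = "LAD")
#' myocardial_jeopardy_index(tr)   # (3 + 1) / 10
#' @export
coronary_tree <- function(branches, lesion_branch,
                          lesion_offset = c("proximal", "mid", "distal")) {
  lesion_offset <- match.arg(lesion_offset)
  need <- c("id", "parent", "vessel", "extent", "significant")
  if (!all(need %in% names(branches)))
    stop("branches must have columns: ", paste(need, collapse = ", "))
  branches$id <- as.character(branches$id)
  branches$parent <- as.character(branches$parent)
  if (anyDuplicated(branches$id)) stop("duplicate branch ids")
  if (any(!is.na(branches$parent) & !(branches$parent %in% branches$id)))
    stop("a branch references a parent id not present in the tree")
  if (any(branches$extent < 0 | branches$extent > 1))
    stop("extent must lie in [0, 1]")
  if (!lesion_branch %in% branches$id)
    stop("lesion_branch '", lesion_branch, "' not found in the tree")
  # acyclicity: walking up from every branch must reach a root
  up <- stats::setNames(branches$parent, branches$id)
  for (b in branches$id) {
    seen <- character(); cur <- b
    while (!is.na(up[[cur]])) {
      if (cur %in% seen) stop("tree contains a cycle through branch '", cur, "'")
      seen <- c(seen, cur); cur <- up[[cur]]
    }
  }
  structure(list(branches = branches, lesion_branch = lesion_branch,
                 lesion_offset = lesion_offset),
            class = "coronary_tree")
}

#' @export
print.coronary_tree <- function(x, ...) {
  cat(sprintf("Coronary tree: %d branches, lesion %s on '%s'\n",
              nrow(x$branches), x$lesion_offset, x$lesion_branch))
  invisible(x)
}

#' Size score of one coronary branch
#'
#' A branch scores 3 if it is a large vessel covering more than 2/3 of the
#' base-to-apex distance, 2 for a medium vessel covering between 1/3 and
#' 2/3 (boundaries inclusive), 1 for a small vessel covering less than
#' 1/3, and 0 if the vessel is insignificant.
#'
#' @param extent fraction of base-to-apex distance covered, in `[0, 1]`.
#' @param significant logical.
#' @return integer score 0-3 (vectorised).
#' @export
branch_score <- function(extent, significant) {
  if (any(extent < 0 | extent > 1, na.rm = TRUE))
    stop("extent must lie in [0, 1]")
  score <- ifelse(extent > 2/3, 3L, ifelse(extent >= 1/3, 2L, 1L))
  ifelse(as.logical(significant), score, 0L)
}

# ids of the lesion-bearing branch and all its descendants
.distal_ids <- function(tree) {
  br <- tree$branches
  distal <- tree$lesion_branch
  repeat {
    more <- br$id[!is.na(br$parent) & br$parent %in% distal & !(br$id %in% distal)]
    if (length(more) == 0L) break
    distal <- c(distal, more)
  }
  distal
}

#' Myocardial jeopardy index
#'
#' The total branch score distal to the lesion (the lesion-bearing branch
#' plus all its descendants) divided by the total score of all branches in
#' the tree, giving a fraction in `[0, 1]`. A lesion at the root of a tree
#' that contains every scored branch has MJI 1; a lesion confined to an
#' insignificant twig has MJI 0.
#'
#' @param tree a [coronary_tree()].
#' @return MJI as a fraction in `[0, 1]`.
#' @export
myocardial_jeopardy_index <- function(tree) {
  stopifnot(inherits(tree, "coronary_tree"))
  br <- tree$branches
  scores <- branch_score(br$extent, br$significant)
  total <- sum(scores)
  if (total == 0)
    stop("all branches score 0; the jeopardy index is undefined")
  sum(scores[br$id %in% .distal_ids(tree)]) / total
}

# canonical Duke 6-segment vocabulary -> regexes over free-text vessel names
.duke_patterns <- c(
  LAD      = "^(lad|left anterior descending)",
  diagonal = "diag",
  septal   = "sept",
  LCx      = "^(lcx|circumflex|left circumflex)",
  OM       = "(^om|obtuse marginal)",
  PDA      = "(^pda|posterior descending)"
)

.duke_segment <- function(vessel) {
  v <- tolower(trimws(vessel))
  out <- rep(NA_character_, length(v))
  for (seg in names(.duke_patterns))
    out[is.na(out) & grepl(.duke_patterns[[seg]], v)] <- seg
  out
}

#' Duke jeopardy score
#'
#' A segment-count index of myocardium at risk: 2 points for each of the
#' six canonical Duke segments (LAD, major diagonal, major septal
#' perforator, LCx, major obtuse marginal, posterior descending) that lies
#' distal to the lesion, capped at 12. Branch vessel names are mapped to
#' segments by keyword; unmappable names are skipped with a warning.
#'
#' @param tree a [coronary_tree()].
#' @return integer score in 0-12.
#' @export
duke_jeopardy_score <- function(tree) {
  stopifnot(inherits(tree, "coronary_tree"))
  br <- tree$branches
  distal <- br[br$id %in% .distal_ids(tree), , drop = FALSE]
  seg <- .duke_segment(distal$vessel)
  if (anyNA(seg) && nrow(distal) > 0)
    warning("unmappable vessel name(s) skipped: ",
            paste(unique(distal$vessel[is.na(seg)]), collapse = ", "))
  min(12L, 2L * length(unique(seg[!is.na(seg)])))
}

#' Read and write coronary trees as JSON
#'
#' Schema: `{"branches": [{"id": ..., "parent": ... or null, "vessel": ...,
#' "extent": ..., "significant": ...}], "lesion_branch": ...,
#' "lesion_offset": ...}`.
#'
#' @param path file path.
#' @param tree a [coronary_tree()].
#' @return `read_tree_json()` returns a [coronary_tree()].
#' @export
read_tree_json <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  br <- j$branches
  if (is.null(br$parent)) br$parent <- NA_character_
  br$parent[br$parent %in% c("", "root")] <- NA_character_
  coronary_tree(br, j$lesion_branch,
                if (is.null(j$lesion_offset)) "proximal" else j$lesion_offset)
}

#' @rdname read_tree_json
#' @export
write_tree_json <- function(tree, path) {
  stopifnot(inherits(tree, "coronary_tree"))
  jsonlite::write_json(
    list(branches = tree$branches, lesion_branch = tree$lesion_branch,
         lesion_offset = tree$lesion_offset),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
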