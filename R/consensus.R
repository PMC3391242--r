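# Majority-vote consensus over binary member maps, and map agreement.

.asBinaryMatrix <- function(maps) {
  if (is.matrix(maps)) return(maps)
  stopifnot(is.list(maps), length(maps) >= 1)
  ids <- maps[[1]]$cell_id
  for (m in maps) {
    if (!is.data.frame(m) || !all(c("cell_id", "presence") %in% names(m)))
      stop("each member map needs cell_id and presence columns")
    if (length(m$cell_id) != length(ids) || any(m$cell_id != ids))
      stop("member maps are not aligned to the same cell set")
  }
  mat <- vapply(maps, function(m) as.numeric(m$presence), numeric(length(ids)))
  rownames(mat) <- ids
  mat
}

#' Majority-vote consensus of binary maps
#'
#' Merges an ensemble of binary presence/absence maps into one: a cell is
#' assigned presence only if strictly more than 50% of the members predict
#' presence there. Exact ties on even-sized ensembles therefore fall to
#' absence.
#'
#' @param maps list of aligned member maps (data.frames with `cell_id`,
#'   `presence`), or a cells x members 0/1 matrix with cell ids as rownames.
#' @param members optional character labels of the ensemble members.
#' @return a [ConsensusMap-class].
#' @export
consensusVote <- function(maps, members = NULL) {
  mat <- .asBinaryMatrix(maps)
  if (!all(mat %in% c(0, 1))) stop("member maps must be binary")
  vf <- rowMeans(mat)
  if (is.null(members)) {
    members <- if (is.list(maps))
      vapply(seq_along(maps), function(i) {
        pr <- attr(maps[[i]], "provenance")
        if (is.null(pr)) paste0("member", i)
        else paste(pr$engine, pr$species, pr$repetition,
                   pr$scenario %||% "current", sep = "/")
      }, character(1))
    else paste0("member", seq_len(ncol(mat)))
  }
  new("ConsensusMap", cell_id = as.integer(rownames(mat) %||%
                                             seq_len(nrow(mat))),
      presence = as.integer(vf > 0.5), vote_fraction = vf,
      members = members)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.mapPresence <- function(x) {
  if (is(x, "ConsensusMap")) presence(x)
  else if (is.data.frame(x)) x$presence
  else as.numeric(x)
}

.mapIds <- function(x) {
  if (is(x, "ConsensusMap")) cellIds(x)
  else if (is.data.frame(x)) x$cell_id
  else seq_along(x)
}

#' Coincidence rate of two binary maps
#'
#' Fraction of grid cells on which two binary maps agree, counting
#' coinciding presences and absences alike.
#'
#' @param a,b aligned binary maps ([ConsensusMap-class], data.frame with
#'   `cell_id`/`presence`, or bare 0/1 vectors).
#' @return agreement fraction in [0, 1].
#' @export
coincidenceRate <- function(a, b) {
  pa <- .mapPresence(a); pb <- .mapPresence(b)
  ia <- .mapIds(a); ib <- .mapIds(b)
  if (length(ia) != length(ib) || any(ia != ib))
    stop("maps are not aligned to the same cell set")
  mean(pa == pb)
}
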