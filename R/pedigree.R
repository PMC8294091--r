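#' Pedigree objects
#'
#' A `Pedigree` is a validated three-column table (`id`, `sire`, `dam`) in
#' topological order: every known parent appears as an individual before any
#' of its offspring. Founders have both parents unknown (`NA`). Individuals
#' with exactly one known parent are rejected: the full-sib mating designs
#' this package targets never produce them, and the pedigree dominance
#' relationship requires both parents of both individuals of a pair.
#'
#' @param id character vector of individual identifiers (unique).
#' @param sire,dam character vectors of parent identifiers; `NA`, `""` or
#'   `"0"` mark an unknown parent.
#' @return An object of class `Pedigree`: a `data.frame` with columns
#'   `id`, `sire`, `dam` (character; `NA` = unknown), topologically sorted.
#' @examples
#' ped <- pedigree(c("F1", "P1", "P2"), c("P1", NA, NA), c("P2", NA, NA))
#' ped$id  # parents first after sorting
#' @export
pedigree <- function(id, sire, dam) {
  id   <- as.character(id)
  sire <- .normalize_parent(sire)
  dam  <- .normalize_parent(dam)
  if (length(sire) != length(id) || length(dam) != length(id))
    stop("id, sire and dam must have the same length")
  if (anyDuplicated(id))
    stop("duplicate individual id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  single <- xor(is.na(sire), is.na(dam))
  if (any(single))
    stop("individual(s) with a single known parent: ",
         paste(id[single], collapse = ", "))
  known <- c(sire[!is.na(sire)], dam[!is.na(dam)])
  missing_parents <- setdiff(known, id)
  if (length(missing_parents))
    stop("parent(s) not present as individuals: ",
         paste(missing_parents, collapse = ", "))
  ord <- .ped_toposort(id, sire, dam)
  out <- data.frame(id = id[ord], sire = sire[ord], dam = dam[ord],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("Pedigree", "data.frame")
  out
}

.normalize_parent <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & (x == "" | x == "0")] <- NA_character_
  x
}

# Kahn topological sort; errors on cycles.
.ped_toposort <- function(id, sire, dam) {
  n <- length(id)
  idx <- seq_len(n)
  names(idx) <- id
  si <- ifelse(is.na(sire), NA_integer_, idx[sire])
  di <- ifelse(is.na(dam),  NA_integer_, idx[dam])
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    # take lowest original index first so sorting is deterministic
    v <- queue[1L]
    queue <- queue[-1L]
    ord <- c(ord, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) != n)
    stop("pedigree contains a cycle involving: ",
         paste(id[setdiff(seq_len(n), ord)], collapse = ", "))
  ord
}

#' Read a pedigree from a CSV/TSV file
#'
#' Expects a header with columns `individual`, `sire`, `dam` (aliases `id`
#' and `mother`/`father` are accepted). Unknown parents may be coded as
#' empty fields, `"0"`, or `NA`. Rows are re-sorted topologically, so the
#' file order is irrelevant.
#'
#' @param path path to a delimited text file.
#' @return A [pedigree()] object.
#' @export
read_pedigree <- function(path) {
  dt <- data.table::fread(path, header = TRUE, colClasses = "character",
                          na.strings = c("NA", ""))
  nm <- tolower(names(dt))
  pick <- function(cands) {
    j <- which(nm %in% cands)
    if (!length(j)) stop("pedigree file lacks a column named one of: ",
                         paste(cands, collapse = "/"))
    dt[[j[1L]]]
  }
  pedigree(pick(c("individual", "id", "indiv")),
           pick(c("sire", "father", "parent1")),
           pick(c("dam", "mother", "parent2")))
}

#' @export
print.Pedigree <- function(x, ...) {
  nf <- sum(is.na(x$sire))
  cat(sprintf("Pedigree: %d individuals (%d founders, %d with recorded parents)\n",
              nrow(x), nf, nrow(x) - nf))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' @rdname pedigree
#' @param x object to test.
#' @export
is_founder <- function(x) {
  stopifnot(inherits(x, "Pedigree"))
  is.na(x$sire) & is.na(x$dam)
}
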