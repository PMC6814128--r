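## Pedigree handling: reading, validation, contemporary genetic groups,
## inbreeding, numerator relationship matrix A and its sparse inverse.

#' Read a pedigree file
#'
#' Reads a delimited pedigree file with header columns
#' \code{individual,dam,sire,provenance} (comma- or tab-separated, UTF-8).
#' Unknown parents are encoded as an empty field or \code{"0"}; a missing
#' provenance is encoded as an empty field.
#'
#' @param path Path to the pedigree file.
#' @param sep Field separator; \code{NULL} (default) autodetects comma vs tab
#'   from the header line.
#' @return A data frame with character columns \code{individual}, \code{dam},
#'   \code{sire}, \code{provenance}; unknown parents and missing provenances
#'   are \code{NA}.
#' @export
read_pedigree <- function(path, sep = NULL) {
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr, fixed = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", na.strings = c("", "NA"),
                          quote = "\"", comment.char = "", strip.white = TRUE,
                          encoding = "UTF-8")
  required <- c("individual", "dam", "sire", "provenance")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("pedigree file lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  as_pedigree(df[required])
}

#' Construct a pedigree data frame
#'
#' Validates a data frame of pedigree records: identifiers must be unique,
#' \code{"0"} and \code{""} are treated as unknown, and self-parentage and
#' selfing (dam and sire naming the same real individual) are rejected.
#'
#' @param df Data frame with columns \code{individual}, \code{dam},
#'   \code{sire} and optionally \code{provenance}.
#' @return A validated pedigree data frame (character columns, \code{NA} for
#'   unknown parents / missing provenance).
#' @export
as_pedigree <- function(df) {
  stopifnot(is.data.frame(df))
  if (!all(c("individual", "dam", "sire") %in% names(df)))
    stop("pedigree needs columns individual, dam, sire")
  if (!"provenance" %in% names(df)) df$provenance <- NA_character_
  ped <- data.frame(individual = as.character(df$individual),
                    dam  = as.character(df$dam),
                    sire = as.character(df$sire),
                    provenance = as.character(df$provenance),
                    stringsAsFactors = FALSE)
  for (col in c("dam", "sire", "provenance"))
    ped[[col]][!is.na(ped[[col]]) & ped[[col]] %in% c("", "0")] <- NA_character_
  if (anyNA(ped$individual) || any(ped$individual %in% c("", "0")))
    stop("invalid individual identifier (empty or '0')")
  dup <- duplicated(ped$individual)
  if (any(dup))
    stop("duplicate individual id(s): ",
         paste(unique(ped$individual[dup]), collapse = ", "))
  self <- which(!is.na(ped$dam) & ped$dam == ped$individual |
                !is.na(ped$sire) & ped$sire == ped$individual)
  if (length(self))
    stop("individual listed as its own parent: ",
         paste(ped$individual[self], collapse = ", "))
  selfing <- which(!is.na(ped$dam) & !is.na(ped$sire) & ped$dam == ped$sire)
  if (length(selfing))
    stop("selfing (dam == sire) not supported: ",
         paste(ped$individual[selfing], collapse = ", "))
  ped
}

#' Topologically sort and complete a pedigree
#'
#' Reorders records so that parents precede offspring, inserting any parent
#' that is referenced but not declared as a founder with missing provenance.
#' The sort is stable: an already valid ordering is returned unchanged.
#'
#' @param ped Pedigree data frame (see [as_pedigree()]).
#' @return The sorted, completed pedigree data frame.
#' @export
sort_pedigree <- function(ped) {
  ped <- as_pedigree(ped)
  parents <- setdiff(stats::na.omit(unique(c(ped$dam, ped$sire))),
                     ped$individual)
  if (length(parents)) {
    ped <- rbind(data.frame(individual = parents, dam = NA_character_,
                            sire = NA_character_, provenance = NA_character_,
                            stringsAsFactors = FALSE),
                 ped)
  }
  n <- nrow(ped)
  placed <- logical(n)
  known <- new.env(parent = emptyenv())
  order_out <- integer(0)
  remaining <- seq_len(n)
  repeat {
    ready <- remaining[vapply(remaining, function(i) {
      d <- ped$dam[i]; s <- ped$sire[i]
      (is.na(d) || !is.null(known[[d]])) && (is.na(s) || !is.null(known[[s]]))
    }, logical(1))]
    if (!length(ready)) break
    for (i in ready) known[[ped$individual[i]]] <- TRUE
    order_out <- c(order_out, ready)
    remaining <- setdiff(remaining, ready)
  }
  if (length(remaining)) {
    ## walk parent links from a stuck individual to name one on a cycle
    seen <- character(0)
    cur <- ped$individual[remaining[1L]]
    repeat {
      if (cur %in% seen) break
      seen <- c(seen, cur)
      i <- match(cur, ped$individual)
      nxt <- c(ped$dam[i], ped$sire[i])
      nxt <- nxt[!is.na(nxt) & !(nxt %in% ped$individual[order_out])]
      cur <- nxt[1L]
    }
    stop("parentage cycle detected involving individual '", cur, "'")
  }
  out <- ped[order_out, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Define a contemporary genetic-group scheme
#'
#' @param mode \code{"none"} (no groups), \code{"GC1"} (maternal provenance
#'   groups plus a single phantom paternal pollen group shared by all
#'   provenances) or \code{"GC2"} (maternal and paternal slots both assigned
#'   to the provenance group).
#' @param provenances Character vector of provenance labels the scheme must
#'   cover; group ids are derived from them.  Ignored for \code{mode =
#'   "none"}.
#' @param pollen_group Id of the phantom pollen group (GC1 only).
#' @return An object of class \code{"group_scheme"}.
#' @export
group_scheme <- function(mode = c("none", "GC1", "GC2"), provenances = NULL,
                         pollen_group = "G_pollen") {
  mode <- match.arg(mode)
  if (mode == "none")
    return(structure(list(mode = "none", provenance_groups = character(0),
                          pollen_group = NULL), class = "group_scheme"))
  provenances <- unique(as.character(provenances))
  provenances <- provenances[!is.na(provenances)]
  if (!length(provenances)) stop("group scheme needs provenance labels")
  pg <- paste0("G_", provenances)
  names(pg) <- provenances
  if (mode == "GC1") {
    if (pollen_group %in% pg)
      stop("pollen group id collides with a provenance group id")
    structure(list(mode = "GC1", provenance_groups = pg,
                   pollen_group = pollen_group), class = "group_scheme")
  } else {
    structure(list(mode = "GC2", provenance_groups = pg, pollen_group = NULL),
              class = "group_scheme")
  }
}

#' Augment a pedigree with contemporary genetic groups
#'
#' Replaces unknown parent slots by phantom genetic-group ids according to the
#' scheme, sorts the pedigree, and computes inbreeding coefficients.  Under
#' GC2 both unknown slots of an individual from provenance p point to the
#' provenance group; under GC1 the unknown dam slot points to the provenance
#' group and the unknown sire slot to the common phantom pollen group,
#' reflecting paternal contributions from long-distance pollen flow.
#'
#' Group assignment requires a provenance label: founders without one (e.g.
#' control lots handled by a fixed term) are an error under
#' \code{ungrouped = "error"} (the default) or keep their unknown parents
#' under \code{ungrouped = "keep"}.
#'
#' @param ped Pedigree data frame.
#' @param scheme A [group_scheme()].
#' @param ungrouped How to treat individuals with unknown parent slots but no
#'   provenance label when \code{scheme$mode != "none"}.
#' @return An object of class \code{"augped"}: list with \code{groups}
#'   (character vector of group ids, the first equation block), \code{ped}
#'   (sorted records with slots filled), \code{F} (per-individual inbreeding),
#'   \code{d} (within-family variance coefficients used by the A-inverse) and
#'   \code{scheme}.
#' @export
augment_pedigree <- function(ped, scheme = group_scheme("none"),
                             ungrouped = c("error", "keep")) {
  ungrouped <- match.arg(ungrouped)
  ped <- sort_pedigree(ped)
  mode <- scheme$mode
  groups <- character(0)
  if (mode != "none") {
    labelled <- !is.na(ped$provenance)
    covered <- ped$provenance[labelled] %in% names(scheme$provenance_groups)
    if (!all(covered))
      stop("provenance label(s) not covered by the group scheme: ",
           paste(unique(ped$provenance[labelled][!covered]), collapse = ", "))
    open <- is.na(ped$dam) | is.na(ped$sire)
    if (ungrouped == "error" && any(open & !labelled))
      stop("individual(s) with unknown parents but no provenance label: ",
           paste(ped$individual[open & !labelled], collapse = ", "),
           " (use ungrouped = \"keep\" to leave them ungrouped)")
    fill <- open & labelled
    gp <- unname(scheme$provenance_groups[ped$provenance[fill]])
    if (mode == "GC2") {
      ped$dam[fill][is.na(ped$dam[fill])] <- gp[is.na(ped$dam[fill])]
      ped$sire[fill][is.na(ped$sire[fill])] <- gp[is.na(ped$sire[fill])]
      groups <- unname(scheme$provenance_groups)
    } else { # GC1
      ped$dam[fill][is.na(ped$dam[fill])] <- gp[is.na(ped$dam[fill])]
      ped$sire[fill][is.na(ped$sire[fill])] <- scheme$pollen_group
      groups <- c(unname(scheme$provenance_groups), scheme$pollen_group)
    }
    if (any(groups %in% ped$individual))
      stop("group id(s) collide with individual id(s): ",
           paste(intersect(groups, ped$individual), collapse = ", "))
  }
  n <- nrow(ped)
  idx <- function(x) {
    i <- match(x, ped$individual)            # real parent -> positive index
    i[is.na(i) & !is.na(x) & x %in% groups] <- 0L  # group parent
    i[is.na(x)] <- -1L                       # unknown
    i
  }
  dam_i <- idx(ped$dam); sire_i <- idx(ped$sire)
  ## group parents behave as unrelated non-inbred founders (F = 0)
  Fcoef <- inbreeding_ml(pmax(dam_i, 0L), pmax(sire_i, 0L))
  Fd <- ifelse(dam_i > 0L, Fcoef[pmax(dam_i, 1L)], 0)
  Fs <- ifelse(sire_i > 0L, Fcoef[pmax(sire_i, 1L)], 0)
  ## Mendelian-sampling variance coefficients count REAL known parents only:
  ## a phantom group slot receives A-inverse contributions but, like an
  ## unknown parent, does not reduce the within-family variance (this is what
  ## makes the group equations equivalent to explicit unpenalised group
  ## regressions on expected ancestry fractions)
  known_d <- dam_i > 0L; known_s <- sire_i > 0L
  d <- ifelse(known_d & known_s, 0.5 - 0.25 * (Fd + Fs),
       ifelse(known_d, 0.75 - 0.25 * Fd,
       ifelse(known_s, 0.75 - 0.25 * Fs, 1)))
  structure(list(groups = groups, ped = ped, F = stats::setNames(Fcoef, ped$individual),
                 d = d, dam_i = dam_i, sire_i = sire_i, scheme = scheme),
            class = "augped")
}

#' @export
print.augped <- function(x, ...) {
  cat("Augmented pedigree:", nrow(x$ped), "individuals,",
      length(x$groups), "genetic group(s), scheme", x$scheme$mode, "\n")
  if (length(x$groups)) cat("  groups:", paste(x$groups, collapse = ", "), "\n")
  cat("  mean inbreeding:", format(mean(x$F), digits = 4), "\n")
  invisible(x)
}

## Meuwissen & Luo style recursive inbreeding computation.
## dam/sire are integer indices into the sorted pedigree (0 = unknown or
## phantom group, both treated as unrelated non-inbred founders).
inbreeding_ml <- function(dam, sire, ...) {
  n <- length(dam)
  Fcoef <- numeric(n)
  if (!n) return(Fcoef)
  for (i in seq_len(n)) {
    if (dam[i] == 0L || sire[i] == 0L) { Fcoef[i] <- 0; next }
    ## accumulate relationship between dam and sire by ancestor traversal
    anc <- numeric(n)       # contribution weights per ancestor
    rel <- 0
    d <- dam[i]; s <- sire[i]
    anc[d] <- anc[d] + 0.5
    anc[s] <- anc[s] + 0.5
    ## walk down from the highest index; a(d,s) via tabular decomposition:
    ## A[i,i]-1 = F_i = 0.5 * a(dam, sire); compute a(d,s) by path counting
    rel <- relationship_pair(d, s, dam, sire, Fcoef)
    Fcoef[i] <- 0.5 * rel
  }
  Fcoef
}

## additive relationship between two individuals given F of all earlier ones
relationship_pair <- function(a, b, dam, sire, Fcoef) {
  if (a == 0L || b == 0L) return(0)
  if (a == b) return(1 + Fcoef[a])
  if (a < b) { tmp <- a; a <- b; b <- tmp }   # recurse on the later one
  d <- dam[a]; s <- sire[a]
  0.5 * (relationship_pair(d, b, dam, sire, Fcoef) +
         relationship_pair(s, b, dam, sire, Fcoef))
}

#' Inbreeding coefficients
#'
#' @param aug An [augment_pedigree()] result.
#' @return Named numeric vector of inbreeding coefficients (groups excluded).
#' @export
inbreeding <- function(aug) {
  stopifnot(inherits(aug, "augped"))
  aug$F
}

#' Numerator relationship matrix by the tabular method
#'
#' Dense recursive construction of A over the real individuals of an
#' augmented pedigree; phantom group parents are treated as unknown founders,
#' so A describes relationships through real ancestors only.  Intended as an
#' oracle for small pedigrees.
#'
#' @param aug An [augment_pedigree()] result.
#' @return Dense symmetric matrix with dimnames = individual ids;
#'   diagonal equals 1 + F.
#' @export
build_A_tabular <- function(aug) {
  stopifnot(inherits(aug, "augped"))
  n <- nrow(aug$ped)
  A <- matrix(0, n, n, dimnames = list(aug$ped$individual, aug$ped$individual))
  dam <- pmax(aug$dam_i, 0L); sire <- pmax(aug$sire_i, 0L)
  for (i in seq_len(n)) {
    d <- dam[i]; s <- sire[i]
    if (i > 1L) {
      for (j in seq_len(i - 1L)) {
        aij <- 0
        if (d > 0L) aij <- aij + 0.5 * A[j, d]
        if (s > 0L) aij <- aij + 0.5 * A[j, s]
        A[i, j] <- A[j, i] <- aij
      }
    }
    A[i, i] <- 1 + if (d > 0L && s > 0L) 0.5 * A[d, s] else 0
  }
  A
}

#' Sparse A-inverse with genetic-group equations
#'
#' Assembles the inverse numerator relationship structure over the equation
#' set (groups, individuals) by the Westell-Quaas rules: for individual i with
#' parent slots s and d (each a real individual, a phantom group, or unknown),
#' accumulate \eqn{\delta_i} at (i,i), \eqn{-\delta_i/2} at (i, parent) and
#' \eqn{\delta_i/4} at each parent-pair cell, with
#' \eqn{\delta_i = 1/d_i} and \eqn{d_i = 0.5 - 0.25 (F_s + F_d)} when both
#' slots are filled (a group counts as a known, non-inbred founder),
#' \eqn{d_i = 0.75 - 0.25 F} with a single known slot, and \eqn{d_i = 1} for
#' unknown-parent founders.  Groups receive equations but no prior precision
#' of their own, so they act as unpenalised effects absorbed into breeding
#' values.
#'
#' @param aug An [augment_pedigree()] result.
#' @return Sparse symmetric \code{\link[Matrix]{dsCMatrix-class}} with
#'   dimnames \code{c(groups, individuals)}.
#' @export
build_Ainv_groups <- function(aug) {
  stopifnot(inherits(aug, "augped"))
  ng <- length(aug$groups)
  n <- nrow(aug$ped)
  labels <- c(aug$groups, aug$ped$individual)
  ## equation index: groups 1..ng, individual i -> ng + i
  eq <- function(i) ifelse(i > 0L, ng + i, NA_integer_)
  geq <- match(ifelse(aug$dam_i == 0L, aug$ped$dam, NA), aug$groups)
  seq_ <- match(ifelse(aug$sire_i == 0L, aug$ped$sire, NA), aug$groups)
  dam_eq  <- ifelse(aug$dam_i > 0L, ng + aug$dam_i,
                    ifelse(aug$dam_i == 0L, geq, NA))
  sire_eq <- ifelse(aug$sire_i > 0L, ng + aug$sire_i,
                    ifelse(aug$sire_i == 0L, seq_, NA))
  delta <- 1 / aug$d
  ii <- jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, v)
  }
  self_i <- ng + seq_len(n)
  add(self_i, self_i, delta)
  hasd <- !is.na(dam_eq); hass <- !is.na(sire_eq)
  add(self_i[hasd], dam_eq[hasd], -delta[hasd] / 2)
  add(dam_eq[hasd], self_i[hasd], -delta[hasd] / 2)
  add(self_i[hass], sire_eq[hass], -delta[hass] / 2)
  add(sire_eq[hass], self_i[hass], -delta[hass] / 2)
  add(dam_eq[hasd], dam_eq[hasd], delta[hasd] / 4)
  add(sire_eq[hass], sire_eq[hass], delta[hass] / 4)
  both <- hasd & hass
  add(dam_eq[both], sire_eq[both], delta[both] / 4)
  add(sire_eq[both], dam_eq[both], delta[both] / 4)
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(ng + n, ng + n),
                            dimnames = list(labels, labels))
  Matrix::forceSymmetric((M + Matrix::t(M)) / 2)
}

#' Expected genetic-group ancestry fractions
#'
#' For each individual, the fraction of its expected ancestry tracing to each
#' phantom genetic group, by the recursion row(i) = (row(dam) + row(sire))/2
#' with a group's row its own unit vector and an unknown slot contributing
#' nothing.  Used as the explicit fixed-regression (Q matrix) oracle for the
#' group-augmented equations.
#'
#' @param aug An [augment_pedigree()] result.
#' @return Dense matrix, rows = individuals, columns = groups.  With every
#'   ancestor path terminating in a group, rows sum to 1.
#' @export
build_group_fractions <- function(aug) {
  stopifnot(inherits(aug, "augped"))
  ng <- length(aug$groups)
  n <- nrow(aug$ped)
  Q <- matrix(0, n, ng, dimnames = list(aug$ped$individual, aug$groups))
  if (!ng) return(Q)
  gd <- match(ifelse(aug$dam_i == 0L, aug$ped$dam, NA), aug$groups)
  gs <- match(ifelse(aug$sire_i == 0L, aug$ped$sire, NA), aug$groups)
  for (i in seq_len(n)) {
    row <- numeric(ng)
    if (aug$dam_i[i] > 0L) row <- row + 0.5 * Q[aug$dam_i[i], ]
    else if (!is.na(gd[i])) row[gd[i]] <- row[gd[i]] + 0.5
    if (aug$sire_i[i] > 0L) row <- row + 0.5 * Q[aug$sire_i[i], ]
    else if (!is.na(gs[i])) row[gs[i]] <- row[gs[i]] + 0.5
    Q[i, ] <- row
  }
  Q
}

#' Write an augmented pedigree
#'
#' Emits the group rows first (role \code{"group"}) then the sorted individual
#' records (role \code{"individual"}), unknown slots as empty fields.
#'
#' @param aug An [augment_pedigree()] result.
#' @param path Output file path.
#' @param sep Field separator.
#' @export
write_augmented_pedigree <- function(aug, path, sep = ",") {
  stopifnot(inherits(aug, "augped"))
  gdf <- data.frame(individual = aug$groups, dam = "", sire = "",
                    provenance = "", role = "group", stringsAsFactors = FALSE)
  p <- aug$ped
  p[is.na(p)] <- ""
  p$role <- "individual"
  utils::write.table(rbind(gdf, p), path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

## log|A| of the real-individual relationship matrix (unknown/group parents
## as founders): sum of log within-family variance coefficients.
logdet_A <- function(aug) sum(log(aug$d))
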