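#' Chain contigs through linkage of their most distal markers
#'
#' Each contig contributes two ends (head = first markers in physical
#' order, tail = last). An end is represented by its most distal marker,
#' falling back to the second-most-distal when the distal one is
#' uninformative (fewer than `min_shared` non-missing calls). Edges between
#' ends of different contigs with two-point LOD above `lod_threshold` are
#' accepted greedily in decreasing LOD order, under the constraints that
#' each end joins at most one other end and no cycle is formed; rejected
#' competing edges are reported with a message.
#'
#' @param m a lenient-filtered [geno_matrix()] (markers sorted physically).
#' @param lod_threshold junction threshold (default 5.5).
#' @param min_shared minimum informative overlap.
#' @return object of class `contig_chains`: a list of data.frames
#'   (`contig`, `orientation`, `junction_lod` linking each contig to the
#'   previous one).
#' @export
chain_contigs <- function(m, lod_threshold = 5.5, min_shared = 10) {
  contigs <- unique(m$markers$contig)
  called <- rowSums(!is.na(m$calls) & m$calls != GT_HET)
  ends <- do.call(rbind, lapply(contigs, function(ct) {
    ix <- which(m$markers$contig == ct)
    pick <- function(order_ix) {
      for (i in order_ix) if (called[i] >= min_shared) return(i)
      NA_integer_
    }
    data.frame(contig = ct, side = c("head", "tail"),
               row = c(pick(ix), pick(rev(ix))),
               stringsAsFactors = FALSE)
  }))
  usable <- !is.na(ends$row)
  ne <- nrow(ends)
  lod <- matrix(NA_real_, ne, ne)
  if (any(usable)) {
    tp <- two_point_all(m$calls[ends$row[usable], , drop = FALSE],
                        min_shared = min_shared)
    lod[usable, usable] <- tp$lod
  }
  cand <- which(upper.tri(lod) & lod > lod_threshold, arr.ind = TRUE)
  if (nrow(cand)) {
    cand <- cand[ends$contig[cand[, 1]] != ends$contig[cand[, 2]], ,
                 drop = FALSE]
  }
  ord <- order(-lod[cand])
  cand <- cand[ord, , drop = FALSE]
  parent <- stats::setNames(contigs, contigs)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  end_used <- logical(ne)
  links <- list()
  for (i in seq_len(nrow(cand))) {
    e1 <- cand[i, 1]; e2 <- cand[i, 2]
    c1 <- ends$contig[e1]; c2 <- ends$contig[e2]
    if (end_used[e1] || end_used[e2]) {
      message("chain_contigs: junction ", c1, "/", c2,
              " (LOD ", round(lod[e1, e2], 2), ") rejected: end already used")
      next
    }
    if (find(c1) == find(c2)) {
      message("chain_contigs: junction ", c1, "/", c2,
              " rejected: would close a cycle")
      next
    }
    end_used[c(e1, e2)] <- TRUE
    parent[find(c1)] <- find(c2)
    links[[length(links) + 1]] <- data.frame(
      contig1 = c1, side1 = ends$side[e1],
      contig2 = c2, side2 = ends$side[e2], lod = lod[e1, e2])
  }
  links <- if (length(links)) do.call(rbind, links) else
    data.frame(contig1 = character(), side1 = character(),
               contig2 = character(), side2 = character(), lod = numeric())
  chains <- walk_chains(contigs, links)
  structure(chains, class = "contig_chains")
}

# Read chains off the accepted end-matching: traverse each connected
# component from a contig with a free end, recording orientation (+ means
# ascending physical order along the chain).
walk_chains <- function(contigs, links) {
  deg <- table(factor(c(links$contig1, links$contig2), levels = contigs))
  seen <- stats::setNames(rep(FALSE, length(contigs)), contigs)
  link_for <- function(ct, exclude_row) {
    hit <- which((links$contig1 == ct | links$contig2 == ct) &
                   seq_len(nrow(links)) != exclude_row)
    if (length(hit)) hit[1] else NA_integer_
  }
  chains <- list()
  starts <- c(contigs[deg <= 1], contigs[deg == 2])
  for (start in starts) {
    if (seen[start]) next
    rows <- list()
    ct <- start; prev_row <- 0L; enter_side <- NA_character_
    lod_in <- NA_real_
    repeat {
      seen[ct] <- TRUE
      # orientation: the end used to enter must come first along the chain
      nxt_row <- link_for(ct, prev_row)
      exit_side <- if (!is.na(nxt_row)) {
        if (links$contig1[nxt_row] == ct) links$side1[nxt_row]
        else links$side2[nxt_row]
      } else NA_character_
      orientation <- if (!is.na(enter_side)) {
        if (enter_side == "head") "+" else "-"
      } else if (!is.na(exit_side)) {
        if (exit_side == "tail") "+" else "-"
      } else "+"
      rows[[length(rows) + 1]] <- data.frame(
        contig = ct, orientation = orientation, junction_lod = lod_in,
        stringsAsFactors = FALSE)
      if (is.na(nxt_row)) break
      other <- if (links$contig1[nxt_row] == ct) links$contig2[nxt_row]
      else links$contig1[nxt_row]
      enter_side <- if (links$contig1[nxt_row] == other) links$side1[nxt_row]
      else links$side2[nxt_row]
      lod_in <- links$lod[nxt_row]
      prev_row <- nxt_row
      if (seen[other]) break
      ct <- other
    }
    chains[[length(chains) + 1]] <- do.call(rbind, rows)
  }
  chains[order(-vapply(chains, nrow, integer(1)),
               vapply(chains, function(d) d$contig[1], character(1)))]
}

#' Impute missing calls for the forced-order map
#'
#' Per sample and per contig, a missing call is replaced by the previous
#' (physically preceding) call; a missing run at the start of a contig is
#' filled from the first non-missing call. The imputation boundary is the
#' contig, never the chain. Samples with no calls at all on a contig are
#' left missing and flagged in the `"unimputable"` attribute.
#'
#' @param m a [geno_matrix()] with heterozygous calls already set missing.
#' @return imputed `geno_matrix`.
#' @export
impute_missing_forced <- function(m) {
  calls <- m$calls
  unimputable <- list()
  for (ct in unique(m$markers$contig)) {
    rows <- which(m$markers$contig == ct)
    block <- calls[rows, , drop = FALSE]
    for (s in seq_len(ncol(block))) {
      v <- block[, s]
      obs <- which(!is.na(v))
      if (!length(obs)) {
        unimputable[[length(unimputable) + 1]] <-
          data.frame(contig = ct, sample = colnames(calls)[s])
        next
      }
      f <- findInterval(seq_along(v), obs)
      block[, s] <- v[obs[pmax(f, 1L)]]
    }
    calls[rows, ] <- block
  }
  m$calls <- calls
  attr(m, "unimputable") <- if (length(unimputable))
    do.call(rbind, unimputable) else NULL
  m
}

#' Build the forced-order linkage map
#'
#' Marker order is fixed to physical order within contigs and to the chain
#' order (with orientation) across contigs; centimorgan positions
#' accumulate from adjacent-pair recombination fractions on the imputed
#' matrix. One linkage group per chain, numbered by descending marker
#' count.
#'
#' @param m a lenient-filtered [geno_matrix()]; imputed internally.
#' @param chains a `contig_chains` from [chain_contigs()].
#' @param assembly optional [assembly_index()].
#' @param map_function passed to [map_distance()].
#' @param min_shared minimum informative overlap for an adjacency.
#' @return a `genetic_map`.
#' @export
build_forced_map <- function(m, chains, assembly = NULL,
                             map_function = "haldane", min_shared = 10) {
  mi <- impute_missing_forced(m)
  groups <- lapply(chains, function(ch) {
    rows <- unlist(lapply(seq_len(nrow(ch)), function(i) {
      ix <- which(mi$markers$contig == ch$contig[i])
      if (ch$orientation[i] == "-") rev(ix) else ix
    }))
    if (length(rows) < 2) {
      return(data.frame(id = mi$markers$id[rows],
                        contig = mi$markers$contig[rows],
                        pos = mi$markers$pos[rows], cm = 0,
                        junction = FALSE, stringsAsFactors = FALSE))
    }
    rfs <- vapply(seq_along(rows)[-1], function(i) {
      tp <- two_point_linkage(mi$calls[rows[i - 1], ], mi$calls[rows[i], ],
                              min_shared)
      if (is.na(tp$rf)) 0.5 else tp$rf
    }, numeric(1))
    cm <- c(0, cumsum(map_distance(rfs, map_function)))
    data.frame(id = mi$markers$id[rows], contig = mi$markers$contig[rows],
               pos = mi$markers$pos[rows], cm = cm,
               junction = c(FALSE, mi$markers$contig[rows][-1] !=
                              mi$markers$contig[rows][-length(rows)]),
               stringsAsFactors = FALSE)
  })
  ord <- order(-vapply(groups, nrow, integer(1)),
               vapply(groups, function(d) d$contig[1], character(1)))
  new_genetic_map(groups[ord], assembly)
}

#' Write contig chains as TSV
#' @param chains a `contig_chains`.
#' @param path output path.
#' @export
write_chains_tsv <- function(chains, path) {
  rows <- do.call(rbind, lapply(seq_along(chains), function(i) {
    d <- chains[[i]]; d$chain_id <- i; d
  }))
  utils::write.table(rows[c("chain_id", "contig", "orientation",
                            "junction_lod")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
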