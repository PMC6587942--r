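## Pedigree classification of haplotype blocks: family-shared,
## parent-specific inherited, recombined (a segment-wise mosaic of the two
## parents), or other; plus the accounting report and subgenome tally.

#' Compare two samples' haplotype strings in a block
#'
#' @param block one block from a `haplotype_blocks` list.
#' @param sample1,sample2 sample ids.
#' @return `TRUE` iff both strings are present (non-missing) and
#'   identical; a missing (`NA`) string never matches.
#' @export
block_haplotype_equal <- function(block, sample1, sample2) {
  h <- block$haplotypes
  if (!sample1 %in% names(h) || !sample2 %in% names(h))
    hb_stop("unknown sample in block haplotypes", "hb_invalid")
  !is.na(h[[sample1]]) && !is.na(h[[sample2]]) &&
    h[[sample1]] == h[[sample2]]
}

## minimal alternating two-parent mosaic of `f`:
## returns integer breakpoint positions (split after SNP i), or NULL when
## no mosaic exists. Suffix DP; reconstruction picks the leftmost switch
## among minimal solutions.
mosaic_breakpoints <- function(f, a, b) {
  L <- length(f)
  par <- list(a, b)
  ## reach[i, p]: furthest j with par[[p]][i..j] == f[i..j]
  reach <- matrix(0L, L + 1, 2)
  for (p in 1:2) {
    r <- integer(L + 1)
    r[L + 1] <- L  # sentinel
    for (i in L:1) {
      r[i] <- if (f[i] != par[[p]][i]) i - 1L
              else if (i == L) L else max(i, r[i + 1])
    }
    reach[, p] <- r
  }
  INF <- L + 10L
  minsw <- matrix(INF, L + 2, 2)  # minsw[i, p]: switches covering f[i..L]
  minsw[L + 1, ] <- -1L           # phantom: segment ended exactly at L
  for (i in L:1) {
    for (p in 1:2) {
      rp <- reach[i, p]
      if (rp < i) next
      if (rp == L) { minsw[i, p] <- 0L; next }
      ## must switch somewhere in [i, rp]; all choices reach other parent
      ## at s+1; min over s of 1 + minsw[s+1, other]
      cand <- minsw[(i + 1):(rp + 1), 3 - p]
      best <- min(cand)
      if (best < INF) minsw[i, p] <- 1L + best
    }
  }
  start_p <- which.min(minsw[1, ])
  if (minsw[1, start_p] >= INF || minsw[1, start_p] < 1) {
    ## 0 switches means f equals a parent outright -- not a mosaic
    if (minsw[1, 1] == 0L || minsw[1, 2] == 0L) return(NULL)
    return(NULL)
  }
  ## reconstruct, leftmost switch first among minimal continuations
  bps <- integer(0)
  i <- 1L; p <- start_p
  while (minsw[i, p] > 0L) {
    rp <- reach[i, p]
    for (s in i:rp) {
      if (minsw[s + 1, 3 - p] == minsw[i, p] - 1L) {
        bps <- c(bps, s)
        i <- s + 1L; p <- 3L - p
        break
      }
    }
  }
  bps
}

#' Classify haplotype blocks across the pedigree
#'
#' Applies, per block and in priority order:
#'
#' 1. `family_shared` -- all family members (both parents, focal, all
#'    progeny) carry identical haplotype strings;
#' 2. `parentA_inherited` / `parentB_inherited` -- the focal string equals
#'    exactly one parent's and all required progeny match the focal
#'    string;
#' 3. `recombined` -- the focal string matches neither parent in full but
#'    splits at >= 1 SNP boundary into contiguous segments, alternating
#'    between the two parents, each matching that parent's sub-string,
#'    with all required progeny matching the focal string (minimal
#'    breakpoints, leftmost on ties);
#' 4. `other` -- anything else, including blocks with missing strings.
#'
#' @param blocks a `haplotype_blocks` list carrying strings for all
#'   pedigree samples.
#' @param pedigree a [pedigree_spec].
#' @param min_progeny number of progeny that must match the focal string
#'   for the inherited/recombined calls (default: all of them).
#' @return data.frame of class `block_classification`: `block_id`,
#'   `category`, `breakpoints` (semicolon-joined split-after-SNP indices,
#'   `""` if none), `reason`.
#' @export
classify_blocks <- function(blocks, pedigree,
                            min_progeny = length(pedigree$progeny)) {
  fam <- family_ids(pedigree)
  rows <- lapply(blocks, function(b) {
    out <- data.frame(block_id = b$block_id, category = "other",
                      breakpoints = "", reason = "",
                      stringsAsFactors = FALSE)
    h <- b$haplotypes
    if (!all(fam %in% names(h))) {
      out$reason <- "pedigree sample missing from block haplotypes"
      return(out)
    }
    h <- h[fam]
    if (anyNA(h)) {
      out$reason <- sprintf("missing haplotype string: %s",
                            paste(fam[is.na(h)], collapse = ","))
      return(out)
    }
    hf <- h[[pedigree$focal]]
    ha <- h[[pedigree$parentA]]; hb <- h[[pedigree$parentB]]
    prog_match <- sum(h[pedigree$progeny] == hf)
    if (all(h == h[[1]])) {
      out$category <- "family_shared"
      return(out)
    }
    if (prog_match >= min_progeny) {
      if (hf == ha && hf != hb) {
        out$category <- "parentA_inherited"
        return(out)
      }
      if (hf == hb && hf != ha) {
        out$category <- "parentB_inherited"
        return(out)
      }
      if (hf != ha && hf != hb) {
        bps <- mosaic_breakpoints(strsplit(hf, "")[[1]],
                                  strsplit(ha, "")[[1]],
                                  strsplit(hb, "")[[1]])
        if (!is.null(bps) && length(bps) >= 1) {
          out$category <- "recombined"
          out$breakpoints <- paste(bps, collapse = ";")
          return(out)
        }
        out$reason <- "focal matches neither parent nor a two-parent mosaic"
        return(out)
      }
      out$reason <- "focal matches both parents but family not uniform"
      return(out)
    }
    out$reason <- sprintf("only %d/%d progeny match focal", prog_match,
                          length(pedigree$progeny))
    out
  })
  res <- do.call(rbind, rows)
  class(res) <- c("block_classification", "data.frame")
  res
}

#' Pedigree accounting report
#'
#' Counts blocks per category and reports proportions. Following the
#' published accounting convention for this pedigree design, the
#' family-shared proportion is taken against the total number of blocks,
#' while the parent-specific inherited proportions are taken against an
#' explicit `parent_denominator` -- by default the family-shared count,
#' the denominator used in the printed fractions this report mirrors.
#' Percentages are rounded half-up to 2 decimals and always recompute
#' exactly from the integer counts.
#'
#' @param x a `block_classification` data.frame, or a named numeric vector
#'   of counts (`family_shared`, `parentA_inherited`, `parentB_inherited`,
#'   `recombined`, `other`; missing names count 0).
#' @param total_blocks denominator for the family-shared (and recombined)
#'   proportion; default: sum of category counts.
#' @param parent_denominator denominator for the parent-specific
#'   proportions; default: the family-shared count. A zero denominator
#'   flags the proportion as `NA`.
#' @return list of class `family_report` with `counts`, `total_blocks`,
#'   `parent_denominator` and `pct` (named percentages).
#' @export
family_report <- function(x, total_blocks = NULL,
                          parent_denominator = NULL) {
  cats <- c("family_shared", "parentA_inherited", "parentB_inherited",
            "recombined", "other")
  if (inherits(x, "block_classification") || is.data.frame(x)) {
    if (nrow(x) == 0) hb_stop("no classifications", "hb_invalid")
    counts <- setNames(vapply(cats, function(k) sum(x$category == k), 0),
                       cats)
  } else {
    counts <- setNames(rep(0, length(cats)), cats)
    counts[names(x)] <- x
  }
  if (is.null(total_blocks)) total_blocks <- sum(counts)
  if (is.null(parent_denominator))
    parent_denominator <- counts[["family_shared"]]
  pct <- c(family_shared = pct_of(counts[["family_shared"]], total_blocks),
           parentA_inherited = pct_of(counts[["parentA_inherited"]],
                                      parent_denominator),
           parentB_inherited = pct_of(counts[["parentB_inherited"]],
                                      parent_denominator),
           recombined = pct_of(counts[["recombined"]], total_blocks),
           other = pct_of(counts[["other"]], total_blocks))
  structure(list(counts = counts, total_blocks = total_blocks,
                 parent_denominator = parent_denominator, pct = pct),
            class = "family_report")
}

#' @export
print.family_report <- function(x, ...) {
  cat(sprintf("family_report (total blocks: %d)\n", x$total_blocks))
  den <- c(family_shared = x$total_blocks,
           parentA_inherited = x$parent_denominator,
           parentB_inherited = x$parent_denominator,
           recombined = x$total_blocks, other = x$total_blocks)
  for (k in names(x$counts)) {
    cat(sprintf("  %-18s %6d / %6d  (%s%%)\n", k, x$counts[[k]], den[[k]],
                ifelse(is.na(x$pct[[k]]), "NA",
                       format(x$pct[[k]], nsmall = 2))))
  }
  invisible(x)
}

#' Write a family report as a key-value file
#'
#' @param report a [family_report()] result.
#' @param path output file (`key<TAB>value` lines).
#' @return `path`, invisibly.
#' @export
write_family_report <- function(report, path) {
  kv <- c(setNames(as.character(report$counts),
                   paste0("n_", names(report$counts))),
          total_blocks = as.character(report$total_blocks),
          parent_denominator = as.character(report$parent_denominator),
          setNames(ifelse(is.na(report$pct), "NA",
                          format(report$pct, nsmall = 2, trim = TRUE)),
                   paste0("pct_", names(report$pct))))
  writeLines(paste(names(kv), kv, sep = "\t"), path)
  invisible(path)
}

#' Tally blocks by subgenome
#'
#' @param blocks a `haplotype_blocks` list (or its `as.data.frame()`).
#' @param subgenome_map named character vector mapping each chromosome to
#'   `"At"` or `"Dt"`; by default chromosomes beginning with `A`/`D` map
#'   to `At`/`Dt` (the allotetraploid cotton convention).
#' @return data.frame with `subgenome`, `n_blocks`, `pct` (half-up, 2
#'   decimals).
#' @export
subgenome_tally <- function(blocks, subgenome_map = NULL) {
  df <- if (is.data.frame(blocks)) blocks else as.data.frame(blocks)
  chroms <- unique(df$chrom)
  if (is.null(subgenome_map)) {
    subgenome_map <- setNames(ifelse(startsWith(chroms, "A"), "At",
                                     ifelse(startsWith(chroms, "D"), "Dt",
                                            NA_character_)), chroms)
  }
  if (!all(chroms %in% names(subgenome_map)) ||
      anyNA(subgenome_map[chroms]))
    hb_stop(sprintf("unmapped chromosome(s): %s",
                    paste(chroms[!chroms %in% names(subgenome_map) |
                                 is.na(subgenome_map[chroms])],
                          collapse = ", ")), "hb_invalid")
  sg <- subgenome_map[df$chrom]
  data.frame(subgenome = c("At", "Dt"),
             n_blocks = c(sum(sg == "At"), sum(sg == "Dt")),
             pct = c(pct_of(sum(sg == "At"), nrow(df)),
                     pct_of(sum(sg == "Dt"), nrow(df))))
}

#' Write block classifications as TSV
#'
#' @param classifications a `block_classification` data.frame.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_classifications <- function(classifications, path) {
  utils::write.table(classifications, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
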