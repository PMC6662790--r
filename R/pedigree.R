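#' Build a synthetic pedigree of kindreds with unrecorded links
#'
#' Generates the family graph described by a [pedigree_spec()]: independent
#' kindreds, hidden third-cousin links joining them (the linking ancestors are
#' marked `recorded = FALSE`, emulating relatives absent from the assembled
#' genealogy), and unrelated singleton founders. Members are returned in an
#' order where parents precede children.
#'
#' @param spec a [pedigree_spec()].
#' @param seed integer seed for the sibship and sex draws.
#' @return a `data.frame` of class `pedigree` with columns `id`, `father`,
#'   `mother` (`NA` for founders), `sex` (1 = male, 2 = female), `kindred`,
#'   `gen`, `recorded`, `married_in`. Attribute `link_pairs` lists, per hidden
#'   link, the two recorded chain-bottom individuals (third cousins) and the
#'   hidden ancestral couple they share.
#' @export
build_pedigree <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "pedigree_spec"))
  with_seed(seed, {
    rows <- list()
    add <- function(id, father, mother, sex, kindred, gen, recorded, married_in = FALSE) {
      rows[[length(rows) + 1L]] <<- data.frame(
        id = id, father = father, mother = mother, sex = sex,
        kindred = kindred, gen = gen, recorded = recorded,
        married_in = married_in, stringsAsFactors = FALSE)
    }

    for (k in seq_along(spec$kindreds)) {
      ks <- spec$kindreds[[k]]
      kname <- paste0("K", k)
      couples <- list()
      for (cpl in seq_len(ks$n_founder_couples)) {
        if (ks$generations == 1L && ks$mean_sibship <= 0) {
          # degenerate: founders never mate
        }
        fid <- sprintf("%s_G1M%d", kname, cpl)
        mid <- sprintf("%s_G1F%d", kname, cpl)
        add(fid, NA, NA, 1L, kname, 1L, TRUE)
        add(mid, NA, NA, 2L, kname, 1L, TRUE)
        if (ks$generations > 1L) couples[[length(couples) + 1L]] <- c(fid, mid)
      }
      g <- 1L
      while (g < ks$generations) {
        nxt <- list(); kid_i <- 0L
        for (cpl in couples) {
          nkids <- stats::rpois(1L, ks$mean_sibship)
          for (j in seq_len(nkids)) {
            kid_i <- kid_i + 1L
            sex <- stats::rbinom(1L, 1L, 0.5) + 1L
            cid <- sprintf("%s_G%dC%d", kname, g + 1L, kid_i)
            add(cid, cpl[1], cpl[2], sex, kname, g + 1L, TRUE)
            if (g + 1L < ks$generations) {
              sid <- sprintf("%s_G%dS%d", kname, g + 1L, kid_i)
              add(sid, NA, NA, 3L - sex, kname, g + 1L, TRUE, married_in = TRUE)
              nxt[[length(nxt) + 1L]] <- if (sex == 1L) c(cid, sid) else c(sid, cid)
            }
          }
        }
        if (g + 1L < ks$generations && length(nxt) == 0L)
          stop_fs(sprintf("impossible pedigree spec: kindred %d died out at generation %d",
                          k, g + 1L))
        couples <- nxt
        g <- g + 1L
      }
    }

    ped <- do.call(rbind, rows)

    link_pairs <- NULL
    if (spec$n_third_cousin_links > 0) {
      bottoms <- character(2)
      lp <- list()
      for (j in seq_len(spec$n_third_cousin_links)) {
        hf <- sprintf("L%d_A0M", j); hm <- sprintf("L%d_A0F", j)
        add(hf, NA, NA, 1L, NA_character_, 0L, FALSE)
        add(hm, NA, NA, 2L, NA_character_, 0L, FALSE)
        targets <- c(j, j + 1L)
        for (s in 1:2) {
          side <- c("A", "B")[s]
          k <- targets[s]
          if (spec$kindreds[[k]]$generations < 3L)
            stop_fs("third-cousin links require linked kindreds with >= 3 generations")
          pf <- hf; pm <- hm
          for (t in 1:3) {
            cid <- sprintf("L%d_%s%d", j, side, t)
            sid <- sprintf("L%d_%s%dS", j, side, t)
            add(cid, pf, pm, 1L, NA_character_, 0L, FALSE)
            add(sid, NA, NA, 2L, NA_character_, 0L, FALSE)
            pf <- cid; pm <- sid
          }
          # chain bottom: replaces a married-in spouse in the target kindred
          kname <- paste0("K", k)
          cand <- vapply(rows, function(r) r$married_in && identical(r$kindred, kname) &&
                           r$gen == 2L, logical(1))
          cand_ids <- vapply(rows[cand], `[[`, "", "id")
          if (length(cand_ids) == 0L)
            stop_fs(sprintf("kindred %d has no generation-2 married-in spouse to host a link", k))
          ped_now <- do.call(rbind, rows)
          nchild <- vapply(cand_ids, function(id)
            sum(ped_now$father == id | ped_now$mother == id, na.rm = TRUE), 0L)
          repl <- cand_ids[order(-nchild, cand_ids)][1]
          repl_row <- which(vapply(rows, function(r) r$id == repl, logical(1)))
          repl_sex <- rows[[repl_row]]$sex
          bid <- sprintf("L%d_%s4", j, side)
          add(bid, pf, pm, repl_sex, kname, 2L, TRUE)
          # reassign the replaced spouse's children, then drop the spouse
          for (ri in seq_along(rows)) {
            if (identical(rows[[ri]]$father, repl)) rows[[ri]]$father <- bid
            if (identical(rows[[ri]]$mother, repl)) rows[[ri]]$mother <- bid
          }
          rows[[repl_row]] <- NULL
          bottoms[s] <- bid
        }
        lp[[j]] <- data.frame(link = j, bottom_a = bottoms[1], bottom_b = bottoms[2],
                              hidden_father = hf, hidden_mother = hm,
                              kindred_a = paste0("K", targets[1]),
                              kindred_b = paste0("K", targets[2]),
                              stringsAsFactors = FALSE)
      }
      link_pairs <- do.call(rbind, lp)
    }

    for (u in seq_len(spec$n_unrelated))
      add(sprintf("U%03d", u), NA, NA, stats::rbinom(1L, 1L, 0.5) + 1L,
          "U", 1L, TRUE)

    ped <- do.call(rbind, rows)
    ped <- sort_pedigree(ped)
    attr(ped, "link_pairs") <- link_pairs
    class(ped) <- c("pedigree", "data.frame")
    validate_pedigree(ped)
  })
}

# topological order: founders first, then by depth below founders
sort_pedigree <- function(ped) {
  depth <- stats::setNames(rep(NA_integer_, nrow(ped)), ped$id)
  get_depth <- function(id) {
    if (!is.na(depth[[id]])) return(depth[[id]])
    r <- ped[ped$id == id, ]
    d <- if (is.na(r$father) && is.na(r$mother)) 0L else
      1L + max(get_depth(r$father), get_depth(r$mother))
    depth[[id]] <<- d
    d
  }
  for (id in ped$id) get_depth(id)
  ped[order(depth[ped$id], ped$id), , drop = FALSE]
}

#' Validate pedigree structure
#'
#' Checks acyclicity (parents precede children in the stored order), parent
#' sexes (fathers male, mothers female) and id uniqueness.
#'
#' @param ped a `pedigree` data.frame.
#' @return `ped`, invisibly, or an error.
#' @export
validate_pedigree <- function(ped) {
  if (anyDuplicated(ped$id)) stop_fs("duplicate pedigree ids")
  seen <- character(0)
  sex <- stats::setNames(ped$sex, ped$id)
  for (i in seq_len(nrow(ped))) {
    f <- ped$father[i]; m <- ped$mother[i]
    if (is.na(f) != is.na(m)) stop_fs("members must have both or neither parent")
    if (!is.na(f)) {
      if (!(f %in% seen) || !(m %in% seen))
        stop_fs("pedigree not in parent-first order (cycle or missing parent): ", ped$id[i])
      if (sex[[f]] != 1L) stop_fs("father ", f, " is not male")
      if (sex[[m]] != 2L) stop_fs("mother ", m, " is not female")
    }
    seen <- c(seen, ped$id[i])
  }
  invisible(ped)
}

#' Founder ids of a pedigree
#' @param ped a `pedigree`.
#' @return character vector of ids with no recorded parents.
#' @export
pedigree_founders <- function(ped) ped$id[is.na(ped$father) & is.na(ped$mother)]

#' Minimal pedigree connecting a cousin pair of given degree
#'
#' Builds a pedigree in which two individuals (`PX`, `PY`) are cousins of the
#' requested degree: they descend from one common ancestral couple through
#' chains of `degree + 1` meioses each, every other ancestor being a distinct
#' founder. `degree = 0` yields full siblings. Used for identity-by-descent
#' calibration.
#'
#' @param degree cousin degree (third cousins = 3; 0 = full siblings).
#' @return a `pedigree` data.frame; attribute `pair` holds the two ids.
#' @export
cousin_pair_pedigree <- function(degree) {
  if (!is_count(degree)) stop_fs("degree must be a non-negative integer")
  rows <- list(
    data.frame(id = "A0M", father = NA, mother = NA, sex = 1L,
               kindred = "C", gen = 0L, recorded = FALSE, married_in = FALSE),
    data.frame(id = "A0F", father = NA, mother = NA, sex = 2L,
               kindred = "C", gen = 0L, recorded = FALSE, married_in = FALSE))
  for (side in c("X", "Y")) {
    pf <- "A0M"; pm <- "A0F"
    for (t in seq_len(degree)) {
      cid <- sprintf("%s%d", side, t); sid <- sprintf("%s%dS", side, t)
      rows[[length(rows) + 1L]] <- data.frame(id = cid, father = pf, mother = pm,
        sex = 1L, kindred = "C", gen = t, recorded = FALSE, married_in = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(id = sid, father = NA, mother = NA,
        sex = 2L, kindred = "C", gen = t, recorded = FALSE, married_in = TRUE)
      pf <- cid; pm <- sid
    }
    rows[[length(rows) + 1L]] <- data.frame(id = paste0("P", side), father = pf,
      mother = pm, sex = 1L, kindred = "C", gen = degree + 1L, recorded = TRUE,
      married_in = FALSE)
  }
  ped <- do.call(rbind, rows)
  class(ped) <- c("pedigree", "data.frame")
  attr(ped, "pair") <- c("PX", "PY")
  validate_pedigree(ped)
  ped
}
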