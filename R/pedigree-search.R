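#' Greedy random pedigree under mating constraints
#'
#' Builds one candidate pedigree: offspring are visited in a uniformly
#' random order, and each is assigned the highest-scoring (sire, dam)
#' option whose addition keeps every named parent within `max_mates`
#' distinct mates. A family with a missing partner counts as one mating for
#' the named parent, and all offspring sharing the same (parent, missing)
#' assignment form a single family. Offspring with no feasible positive
#' option are assigned both parents missing (zero LOD contribution). Equal
#' scores are tie-broken uniformly at random within the call.
#'
#' @param options Named list (by offspring) of option data frames with
#'   columns `sire_id`, `dam_id`, `lod`, sorted by decreasing `lod`
#'   (see [pedigree_options()]).
#' @param max_mates Maximum distinct mates per parent: 1 for a full-sib
#'   pedigree, 2 for a half-sib pedigree, `Inf` for unrestricted.
#' @return A `pedigree_solution`: list with `assignments` (data frame
#'   `offspring_id`, `sire_id`, `dam_id`, `lod`), `total_lod`, `max_mates`.
#' @export
greedy_random_pedigree <- function(options, max_mates = Inf) {
  stopifnot(max_mates >= 1)
  n <- length(options)
  offspring <- names(options)
  mates <- new.env(parent = emptyenv())
  out_s <- out_d <- rep(NA_character_, n)
  out_l <- rep(0, n)
  names(out_s) <- names(out_d) <- names(out_l) <- offspring
  for (o in offspring[sample.int(n)]) {
    opts <- options[[o]]
    k <- nrow(opts)
    if (k == 0L) next
    idx <- seq_len(k)
    if (k > 1L && anyDuplicated(opts$lod))
      idx <- order(-opts$lod, stats::runif(k))
    for (i in idx) {
      s <- opts$sire_id[i]; d <- opts$dam_id[i]
      if (mating_feasible(mates, s, d, max_mates)) {
        out_s[o] <- s; out_d[o] <- d; out_l[o] <- opts$lod[i]
        register_mating(mates, s, d)
        break
      }
    }
  }
  assignments <- data.frame(offspring_id = offspring, sire_id = out_s,
                            dam_id = out_d, lod = out_l,
                            row.names = NULL, stringsAsFactors = FALSE)
  structure(list(assignments = assignments, total_lod = sum(out_l),
                 max_mates = max_mates, restart_index = NA_integer_),
            class = "pedigree_solution")
}

partner_key <- function(id) if (is.na(id)) ".missing" else id

mating_feasible <- function(mates, s, d, max_mates) {
  if (is.infinite(max_mates)) return(TRUE)
  ok <- TRUE
  if (!is.na(s)) {
    ms <- mates[[paste0("S:", s)]]
    ok <- partner_key(d) %in% ms || length(ms) < max_mates
  }
  if (ok && !is.na(d)) {
    md <- mates[[paste0("D:", d)]]
    ok <- partner_key(s) %in% md || length(md) < max_mates
  }
  ok
}

register_mating <- function(mates, s, d) {
  if (!is.na(s)) {
    key <- paste0("S:", s)
    mates[[key]] <- union(mates[[key]], partner_key(d))
  }
  if (!is.na(d)) {
    key <- paste0("D:", d)
    mates[[key]] <- union(mates[[key]], partner_key(s))
  }
  invisible(NULL)
}

#' Stochastic search for a maximum-LOD constrained pedigree
#'
#' Samples `n_restarts` independent greedy random pedigrees and retains the
#' one with the highest total LOD. Each restart draws from its own seeded
#' stream derived from `seed`, so results are reproducible and the restart
#' index of the incumbent solution is meaningful.
#'
#' @inheritParams greedy_random_pedigree
#' @param n_restarts Number of independent random pedigrees (default 5000).
#' @param seed Integer master seed; `NULL` uses the current RNG state.
#' @return The best `pedigree_solution` found, with `restart_index` set.
#' @export
stochastic_search <- function(options, max_mates = Inf, n_restarts = 5000,
                              seed = NULL) {
  stopifnot(n_restarts >= 1)
  if (!is.null(seed)) set.seed(seed)
  restart_seeds <- sample.int(.Machine$integer.max, n_restarts)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(restart_seeds[r])
    sol <- greedy_random_pedigree(options, max_mates)
    if (is.null(best) || sol$total_lod > best$total_lod) {
      sol$restart_index <- r
      best <- sol
    }
  }
  validate_pedigree(best)
  best
}

validate_pedigree <- function(sol) {
  a <- sol$assignments
  fam <- unique(a[!is.na(a$sire_id) | !is.na(a$dam_id),
                  c("sire_id", "dam_id")])
  n_s <- table(fam$sire_id[!is.na(fam$sire_id)])
  n_d <- table(fam$dam_id[!is.na(fam$dam_id)])
  if (length(n_s) && max(n_s) > sol$max_mates ||
      length(n_d) && max(n_d) > sol$max_mates)
    stop("internal error: pedigree violates mating constraint")
  invisible(sol)
}

#' @export
print.pedigree_solution <- function(x, ...) {
  s <- pedigree_summary(x)
  cat(sprintf(paste0("<pedigree_solution: %d offspring, %d families, ",
                     "total LOD %.1f, max mates %s>\n"),
              nrow(x$assignments), s$n_families, x$total_lod,
              format(x$max_mates)))
  invisible(x)
}

#' Summarise a pedigree solution
#'
#' Counts families (distinct assigned parent pairs, including pairs with
#' one missing member), distinct named sires and dams, families with a
#' missing sire or dam, the largest family size, and the total LOD.
#'
#' @param sol A `pedigree_solution`.
#' @return One-row data frame of summary counts.
#' @export
pedigree_summary <- function(sol) {
  a <- sol$assignments
  in_fam <- !is.na(a$sire_id) | !is.na(a$dam_id)
  key <- paste(partner_keys(a$sire_id), partner_keys(a$dam_id))[in_fam]
  fam_sizes <- if (length(key)) table(key) else integer()
  fam <- unique(a[in_fam, c("sire_id", "dam_id")])
  data.frame(
    n_families = nrow(fam),
    n_sires = length(unique(stats::na.omit(fam$sire_id))),
    n_dams = length(unique(stats::na.omit(fam$dam_id))),
    n_missing_sire = sum(is.na(fam$sire_id)),
    n_missing_dam = sum(is.na(fam$dam_id)),
    n_unassigned = sum(!in_fam),
    largest_family = if (length(fam_sizes)) max(fam_sizes) else 0L,
    total_lod = sol$total_lod)
}

partner_keys <- function(ids) ifelse(is.na(ids), ".missing", ids)
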