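#' Build a two-founder advanced intercross line pedigree
#'
#' Constructs a multigenerational pedigree emulating an AIL breeding design:
#' generation 0 holds the two inbred founders (one per strain), generation 1
#' is the F1, and each later generation is produced by random pairing of the
#' previous generation's animals, avoiding full-sibling matings when possible.
#' Each pair produces one litter of `offspring_per_pair` pups of random sex.
#'
#' @param n_families Number of breeding pairs maintained per generation
#'   (>= 2).
#' @param n_generations Index of the last generation to breed (>= 2); the F2
#'   is generation 2.
#' @param offspring_per_pair Litter size per breeding pair.
#' @param seed Integer seed; the pedigree is a deterministic function of the
#'   arguments.
#' @return A `data.frame` of class `ail_pedigree` with columns
#'   `individual_id`, `sire_id`, `dam_id` (`NA` for founders), `sex`
#'   (`"male"`/`"female"`) and `generation`.
#' @examples
#' ped <- build_ail_pedigree(5, 4, 4, seed = 1)
#' table(ped$generation)
#' @export
build_ail_pedigree <- function(n_families, n_generations, offspring_per_pair,
                               seed = 1L) {
  stopifnot(n_families >= 2, n_generations >= 2, offspring_per_pair >= 1)
  rng <- local_rng(seed)

  founders <- data.frame(
    individual_id = c("F0_A", "F0_B"),
    sire_id = NA_character_, dam_id = NA_character_,
    sex = c("male", "female"), generation = 0L,
    stringsAsFactors = FALSE
  )
  gens <- list(founders)

  # F1: one litter from the founder pair, sized to seed n_families pairs.
  n_f1 <- max(2L * n_families, 4L)
  sexes <- sample(rep(c("male", "female"), length.out = n_f1))
  gens[[2]] <- data.frame(
    individual_id = sprintf("F1_%03d", seq_len(n_f1)),
    sire_id = "F0_A", dam_id = "F0_B",
    sex = sexes, generation = 1L, stringsAsFactors = FALSE
  )

  for (g in seq(2L, n_generations)) {
    prev <- gens[[g]]
    pairs <- .mate_pairs(prev, n_families, g)
    n_off <- nrow(pairs) * offspring_per_pair
    off_sex <- sample(rep(c("male", "female"), length.out = n_off))
    gens[[g + 1L]] <- data.frame(
      individual_id = sprintf("F%d_%03d", g, seq_len(n_off)),
      sire_id = rep(pairs$sire, each = offspring_per_pair),
      dam_id = rep(pairs$dam, each = offspring_per_pair),
      sex = off_sex, generation = as.integer(g),
      stringsAsFactors = FALSE
    )
  }

  ped <- do.call(rbind, gens)
  rownames(ped) <- NULL
  class(ped) <- c("ail_pedigree", "data.frame")
  validate_pedigree(ped)
  ped
}

# Random male/female pairing with full-sib avoidance when possible.
.mate_pairs <- function(prev, n_families, generation) {
  males <- prev[prev$sex == "male", , drop = FALSE]
  females <- prev[prev$sex == "female", , drop = FALSE]
  n_pairs <- min(n_families, nrow(males), nrow(females))
  if (n_pairs < 2L) {
    stop("breeding failure at generation ", generation,
         ": fewer than 2 available mating pairs")
  }
  males <- males[sample.int(nrow(males)), , drop = FALSE]
  females <- females[sample.int(nrow(females)), , drop = FALSE]
  sire <- character(n_pairs); dam <- character(n_pairs)
  used_f <- rep(FALSE, nrow(females))
  for (i in seq_len(n_pairs)) {
    m <- males[i, ]
    # prefer an unused female that is not a full sibling
    ok <- !used_f &
      !(females$sire_id %in% m$sire_id & females$dam_id %in% m$dam_id &
          !is.na(m$sire_id))
    j <- if (any(ok)) which(ok)[1L] else which(!used_f)[1L]
    used_f[j] <- TRUE
    sire[i] <- m$individual_id
    dam[i] <- females$individual_id[j]
  }
  data.frame(sire = sire, dam = dam, stringsAsFactors = FALSE)
}

#' Validate an AIL pedigree
#'
#' Checks the pedigree invariants: founders (generation 0) have no parents,
#' every parent appears in an earlier generation, and no individual is its
#' own ancestor.
#'
#' @param ped A pedigree `data.frame` (see [build_ail_pedigree()]).
#' @return `ped`, invisibly, or an error.
#' @export
validate_pedigree <- function(ped) {
  need <- c("individual_id", "sire_id", "dam_id", "sex", "generation")
  if (!all(need %in% names(ped))) {
    stop("pedigree must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(ped$individual_id)) stop("duplicate individual ids")
  founders <- ped$generation == 0L
  if (any(!is.na(ped$sire_id[founders])) || any(!is.na(ped$dam_id[founders]))) {
    stop("founders must have no parents")
  }
  nonf <- !founders
  if (any(is.na(ped$sire_id[nonf])) || any(is.na(ped$dam_id[nonf]))) {
    stop("non-founders must have both parents")
  }
  gen <- stats::setNames(ped$generation, ped$individual_id)
  for (col in c("sire_id", "dam_id")) {
    p <- ped[[col]][nonf]
    if (!all(p %in% ped$individual_id)) stop("parent id not in pedigree")
    if (any(gen[p] >= ped$generation[nonf])) {
      stop("parents must precede offspring in generation order")
    }
  }
  invisible(ped)
}

#' Pedigree kinship matrix (tabular method)
#'
#' Recursive expected kinship coefficients phi(i, j): for individual i with
#' parents (p, q) and any earlier j, phi(i, j) = (phi(p, j) + phi(q, j)) / 2,
#' and phi(i, i) = (1 + phi(p, q)) / 2 so the diagonal is 0.5 (1 + f) with f
#' the inbreeding coefficient. Founders are taken as unrelated and
#' non-inbred.
#'
#' @param ped Pedigree (see [build_ail_pedigree()]).
#' @return Symmetric kinship matrix with individual ids as dimnames.
#' @export
kinship_from_pedigree <- function(ped) {
  validate_pedigree(ped)
  ord <- order(ped$generation)
  ped <- ped[ord, , drop = FALSE]
  ids <- ped$individual_id
  n <- length(ids)
  K <- matrix(0, n, n, dimnames = list(ids, ids))
  idx <- stats::setNames(seq_len(n), ids)
  for (i in seq_len(n)) {
    if (ped$generation[i] == 0L) {
      K[i, i] <- 0.5
    } else {
      p <- idx[[ped$sire_id[i]]]
      q <- idx[[ped$dam_id[i]]]
      if (i > 1L) {
        j <- seq_len(i - 1L)
        K[i, j] <- K[j, i] <- 0.5 * (K[p, j] + K[q, j])
      }
      K[i, i] <- 0.5 * (1 + K[p, q])
    }
  }
  K
}
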