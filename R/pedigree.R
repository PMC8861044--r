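#' Construct a family pedigree with a specified consanguinity loop
#'
#' Builds trio, first-cousin, or double-first-cousin family structures with
#' all ancestors needed for gene dropping materialized as founders. In a
#' first-cousin family the two parents share one grandparental couple
#' (kinship 1/16, child inbreeding coefficient F = 1/16 = 6.25%); in a
#' double-first-cousin family they share both grandparental couples
#' (kinship 1/8, F = 12.5%).
#'
#' @param kind one of `"trio"`, `"first_cousin"`, `"double_first_cousin"`.
#' @param n_children number of children of the focal union (>= 1).
#' @param family_id string prefixed to all sample ids so several families can
#'   be pooled into one cohort.
#' @param child_sexes character vector (`"male"`/`"female"`) recycled over
#'   children; defaults to all male, matching the strong male bias of ASD
#'   ascertainment.
#' @param child_affected logical vector recycled over children; defaults to
#'   all affected.
#' @return An object of class `pedigree`: a tibble with columns `sample_id`,
#'   `father_id`, `mother_id`, `sex`, `affected`, `role`, `family_id`, plus a
#'   `loop` attribute naming the consanguinity type.
#' @examples
#' ped <- build_pedigree("first_cousin")
#' kinship(ped, ped_father(ped), ped_mother(ped)) # 1/16
#' @export
build_pedigree <- function(kind = c("trio", "first_cousin", "double_first_cousin"),
                           n_children = 1L, family_id = "FAM1",
                           child_sexes = "male", child_affected = TRUE) {
  kind <- match.arg(kind)
  stopifnot(n_children >= 1L)
  id <- function(x) paste0(family_id, "_", x)
  row <- function(sid, fa, mo, sex, aff, role) {
    tibble::tibble(sample_id = id(sid),
                   father_id = if (is.na(fa)) NA_character_ else id(fa),
                   mother_id = if (is.na(mo)) NA_character_ else id(mo),
                   sex = sex, affected = aff, role = role,
                   family_id = family_id)
  }
  founders <- switch(kind,
    trio = dplyr::bind_rows(
      row("fa", NA, NA, "male", FALSE, "father"),
      row("mo", NA, NA, "female", FALSE, "mother")),
    first_cousin = dplyr::bind_rows(
      # shared grandparental couple g1a x g1b; their children s1 (paternal
      # grandfather) and s2 (maternal grandmother) marry founders
      row("g1a", NA, NA, "male", FALSE, "great_grandfather"),
      row("g1b", NA, NA, "female", FALSE, "great_grandmother"),
      row("s1", "g1a", "g1b", "male", FALSE, "paternal_grandfather"),
      row("s1w", NA, NA, "female", FALSE, "paternal_grandmother"),
      row("s2", "g1a", "g1b", "female", FALSE, "maternal_grandmother"),
      row("s2h", NA, NA, "male", FALSE, "maternal_grandfather"),
      row("fa", "s1", "s1w", "male", FALSE, "father"),
      row("mo", "s2h", "s2", "female", FALSE, "mother")),
    double_first_cousin = dplyr::bind_rows(
      # the two fathers are brothers (couple 1), the two mothers are sisters
      # (couple 2), so the focal parents share all four grandparents
      row("g1a", NA, NA, "male", FALSE, "great_grandfather1"),
      row("g1b", NA, NA, "female", FALSE, "great_grandmother1"),
      row("g2a", NA, NA, "male", FALSE, "great_grandfather2"),
      row("g2b", NA, NA, "female", FALSE, "great_grandmother2"),
      row("b1", "g1a", "g1b", "male", FALSE, "paternal_grandfather"),
      row("b2", "g1a", "g1b", "male", FALSE, "maternal_grandfather"),
      row("s1", "g2a", "g2b", "female", FALSE, "paternal_grandmother"),
      row("s2", "g2a", "g2b", "female", FALSE, "maternal_grandmother"),
      row("fa", "b1", "s1", "male", FALSE, "father"),
      row("mo", "b2", "s2", "female", FALSE, "mother")))
  sexes <- rep_len(child_sexes, n_children)
  affs <- rep_len(child_affected, n_children)
  kids <- dplyr::bind_rows(lapply(seq_len(n_children), function(i) {
    row(paste0("c", i), "fa", "mo", sexes[i], affs[i], "child")
  }))
  ped <- dplyr::bind_rows(founders, kids)
  attr(ped, "loop") <- switch(kind, trio = "none", kind)
  class(ped) <- c("pedigree", class(ped))
  validate_pedigree(ped)
  ped
}

#' Validate pedigree structural invariants
#'
#' Checks unique sample ids, acyclic and complete parental references (every
#' non-founder has both parents present), and parental sex consistency.
#'
#' @param ped a `pedigree`.
#' @return the pedigree, invisibly; errors on violation.
#' @export
validate_pedigree <- function(ped) {
  if (anyDuplicated(ped$sample_id) > 0) stop("duplicate sample_ids in pedigree")
  has_f <- !is.na(ped$father_id)
  has_m <- !is.na(ped$mother_id)
  if (any(has_f != has_m)) stop("every non-founder needs both parents present")
  if (any(has_f & !(ped$father_id %in% ped$sample_id)))
    stop("father_id not present in pedigree")
  if (any(has_m & !(ped$mother_id %in% ped$sample_id)))
    stop("mother_id not present in pedigree")
  sex_of <- stats::setNames(ped$sex, ped$sample_id)
  if (any(sex_of[ped$father_id[has_f]] != "male"))
    stop("father link points at a non-male member")
  if (any(sex_of[ped$mother_id[has_m]] != "female"))
    stop("mother link points at a non-female member")
  # acyclicity: depth-first walk up must terminate
  for (s in ped$sample_id) {
    seen <- character(0)
    frontier <- s
    while (length(frontier)) {
      if (any(frontier %in% seen)) stop("cycle in parental references")
      seen <- c(seen, frontier)
      i <- match(frontier, ped$sample_id)
      frontier <- stats::na.omit(c(ped$father_id[i], ped$mother_id[i]))
    }
  }
  invisible(ped)
}

#' @rdname build_pedigree
#' @param ped a `pedigree`.
#' @export
ped_founders <- function(ped) ped$sample_id[is.na(ped$father_id)]

#' @rdname build_pedigree
#' @export
ped_children <- function(ped) ped$sample_id[ped$role == "child"]

#' @rdname build_pedigree
#' @export
ped_father <- function(ped) ped$sample_id[ped$role == "father"]

#' @rdname build_pedigree
#' @export
ped_mother <- function(ped) ped$sample_id[ped$role == "mother"]

#' Kinship coefficient between two pedigree members
#'
#' Classical recursive kinship: phi(a, a) = 1/2 (1 + phi(father(a),
#' mother(a))), phi(a, b) = 1/2 (phi(father(a), b) + phi(mother(a), b)) when
#' a is not an ancestor of b. The inbreeding coefficient of a child equals
#' the kinship of its parents: 1/16 for first cousins, 1/8 for double first
#' cousins.
#'
#' @param ped a `pedigree`.
#' @param a,b sample ids.
#' @return numeric kinship coefficient.
#' @export
kinship <- function(ped, a, b) {
  fa <- stats::setNames(ped$father_id, ped$sample_id)
  mo <- stats::setNames(ped$mother_id, ped$sample_id)
  # generation index so recursion always descends
  gen <- stats::setNames(rep(0L, nrow(ped)), ped$sample_id)
  repeat {
    g2 <- ifelse(is.na(fa), 0L, pmax(gen[fa] + 1L, 0L, na.rm = TRUE))
    g2 <- pmax(g2, ifelse(is.na(mo), 0L, gen[mo] + 1L), na.rm = TRUE)
    names(g2) <- ped$sample_id
    if (all(g2 == gen)) break
    gen <- g2
  }
  phi <- function(x, y) {
    if (is.na(x) || is.na(y)) return(0)
    if (x == y) {
      if (is.na(fa[x])) return(0.5)
      return(0.5 * (1 + phi(fa[x], mo[x])))
    }
    # recurse on the member of the later generation
    if (gen[x] < gen[y]) { tmp <- x; x <- y; y <- tmp }
    if (is.na(fa[x])) return(0)
    0.5 * (phi(fa[x], y) + phi(mo[x], y))
  }
  phi(a, b)
}
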