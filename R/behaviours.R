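#' Canonical behaviour labels of the egg-laying ethogram
#'
#' The eight motor elements annotated in egg-laying recordings. `egg_expulsion`
#' marks the moment the egg leaves the ovipositor; `ovipositor_contact`,
#' `burrowing`, `egg_pushing`, `abdomen_curling` and `grooming_terminalia` are
#' the elements of the egg deposition sequence; `abdominal_contortions` is the
#' post-expulsion (ovulation-associated) phase; `proboscis_extension` is a
#' substrate-probing element that occurs throughout. User-defined labels are
#' accepted everywhere but flagged as notes by [validate_ethogram()].
#'
#' @format A character vector of length 8.
#' @export
canonical_behaviours <- c(
  "egg_expulsion",
  "ovipositor_contact",
  "burrowing",
  "egg_pushing",
  "abdomen_curling",
  "grooming_terminalia",
  "abdominal_contortions",
  "proboscis_extension"
)

#' Egg-laying phases
#'
#' The three phases of the egg-laying cycle used in the phase-transition
#' analysis: egg `deposition`, abdominal `contortions` and `exploration`.
#'
#' @format A character vector of length 3.
#' @export
egg_laying_phases <- c("deposition", "contortions", "exploration")

# behaviours whose bouts can chain an ovipositor contact to an egg expulsion
deposition_chain_behaviours <- c(
  "ovipositor_contact", "burrowing", "egg_pushing", "egg_expulsion"
)
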