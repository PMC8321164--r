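#' Action vocabularies for the standard-level hand-hygiene task
#'
#' The standard-level task distinguishes seven actions: touching the faucet
#' with the elbow or the hand, rubbing hands with or without water, applying
#' soap, drying hands, and a catch-all non-hygiene class. The coarse wall
#' classifier works on a condensed three-class vocabulary: faucet-elbow,
#' hand-hygiene (any sink-front hand action), and non-hygiene.
#'
#' The element order of each vocabulary is canonical: it is the deterministic
#' tie-break order used when unit-level votes or averaged confidences tie.
#'
#' @format Character vectors.
#' @export
standard7 <- c("faucet_elbow", "faucet_hand", "rub_water", "rub_nowater",
               "soap", "dry_hands", "non_hygiene")

#' @rdname standard7
#' @export
coarse3 <- c("faucet_elbow", "hand_hygiene", "non_hygiene")

#' Map standard-level actions to the coarse three-class vocabulary
#'
#' `faucet_elbow` maps to itself; the four sink-front hand actions
#' (`faucet_hand`, `rub_water`, `rub_nowater`, `soap`) map to `hand_hygiene`;
#' `dry_hands` and `non_hygiene` map to `non_hygiene`. Drying hands happens
#' in the post-hygiene period and is the chest coarse classifier's job, so it
#' is deliberately kept out of the wall classifier's hand-hygiene class.
#'
#' @param actions character vector of standard-level action names.
#' @return character vector over [coarse3].
#' @export
coarse_map <- function(actions) {
  bad <- setdiff(unique(actions), standard7)
  if (length(bad) > 0) {
    stop("unknown action token(s): ", paste(bad, collapse = ", "))
  }
  out <- rep("non_hygiene", length(actions))
  out[actions == "faucet_elbow"] <- "faucet_elbow"
  out[actions %in% c("faucet_hand", "rub_water", "rub_nowater", "soap")] <-
    "hand_hygiene"
  out
}

check_actions <- function(actions, vocab = standard7) {
  bad <- setdiff(unique(actions), vocab)
  if (length(bad) > 0) {
    stop("unknown action token(s): ", paste(bad, collapse = ", "))
  }
  invisible(actions)
}
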