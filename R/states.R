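#' Tumour immune-phenotype (TIP) state alphabet
#'
#' Phenotype timelines are integer coded: 1 = desert, 2 = excluded,
#' 3 = inflamed, 5 = resolved (tumour rejected), 0 = mouse death/euthanasia.
#' Resolved and death are absorbing. All transition matrices in the package
#' use the state order returned by `tip_states()`.
#'
#' @return `tip_states()` returns the canonical state order (character);
#'   `tip_codes()` the named integer codes in the same order.
#' @export
tip_states <- function() c("desert", "excluded", "inflamed", "resolved", "death")

#' @rdname tip_states
#' @export
tip_codes <- function() {
  c(desert = 1L, excluded = 2L, inflamed = 3L, resolved = 5L, death = 0L)
}

# absorbing integer codes (resolved, death)
absorbing_codes <- function() c(5L, 0L)

code_to_state <- function(code) {
  cd <- tip_codes()
  out <- names(cd)[match(code, cd)]
  if (anyNA(out) && !anyNA(code)) stop("phenotype code outside alphabet {0,1,2,3,5}")
  out
}

state_to_code <- function(state) {
  cd <- tip_codes()
  out <- unname(cd[match(state, names(cd))])
  if (anyNA(out)) stop("unknown phenotype state: ", paste(setdiff(state, names(cd)), collapse = ", "))
  out
}
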