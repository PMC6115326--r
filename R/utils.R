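# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base R's \code{round()} rounds half to even; report columns here follow
#' the half-up convention of the printed reference tables.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return \code{x} rounded half-up to \code{digits} places.
#' @export
roundHalfUp <- function(x, digits = 2L) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Derive a labeled substream seed from a master seed
#'
#' Every source of randomness in the package draws its own seed from the
#' master seed through a stable string label, so adding one generator never
#' perturbs the stream of another. The derivation is a small multiplicative
#' hash over the label's codepoints, reduced modulo 2^31 - 1.
#'
#' @param master integer master seed.
#' @param label character label of the substream.
#' @return An integer seed in [0, 2^31 - 1).
#' @export
substreamSeed <- function(master, label) {
    h <- as.double(master) %% 2147483647
    for (code in utf8ToInt(label))
        h <- (h * 31 + code) %% 2147483647
    as.integer(h)
}

# Evaluate 'expr' under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
    env <- globalenv()
    had <- exists(".Random.seed", envir = env, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = env) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = env)
        else if (exists(".Random.seed", envir = env, inherits = FALSE))
            rm(".Random.seed", envir = env)
    })
    set.seed(seed)
    expr
}

# IUPAC expansion: allowed concrete bases per code letter.
iupacAllowed <- function(letters) {
    map <- Biostrings::IUPAC_CODE_MAP
    strsplit(unname(map[letters]), "")
}

reverseComplementString <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
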