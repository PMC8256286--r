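# Evaluate an expression under a given seed, restoring the caller's RNG
# state afterwards.
.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
    }
    set.seed(seed)
    eval.parent(substitute(expr))
}

# 32-bit FNV-1a over a string; used to fingerprint configurations in
# provenance records (not cryptographic).
.fnv1a <- function(s) {
    mul32 <- function(a, b) {
        lo <- a %% 65536
        hi <- a %/% 65536
        (((hi * b) %% 65536) * 65536 + lo * b) %% 4294967296
    }
    h <- 2166136261
    for (byte in utf8ToInt(s)) {
        low <- h %% 256
        h <- h - low + bitwXor(as.integer(low), as.integer(byte))
        h <- mul32(h, 16777619)
    }
    sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

.configHash <- function(config) {
    .fnv1a(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
        force = TRUE))
}
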