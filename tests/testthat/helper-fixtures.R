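# Shared fixtures: a small two-chromosome genome keeps unit tests fast;
# acceptance tests build the full-size genome themselves.

tinyLengths <- function() c(chrA = 200000, chrB = 120000)

tinyMap <- function(n = 600, seed = 11) {
  buildParentalMap(n, tinyLengths(), seed = seed)
}

tinyGmap <- function(rate = 0.345) uniformGeneticMap(rate, tinyLengths())

# a hand-built mosaic: chrA BY then AWRI from 100,001; chrB all AWRI
tinyMosaic <- function() {
  Mosaic(data.frame(chrom = c("chrA", "chrA", "chrB"),
                    start = c(1, 100001, 1),
                    end = c(100000, 200000, 120000),
                    origin = c("BY", "AWRI", "AWRI")),
         tinyLengths())
}

suppressMarkerMessages <- function(expr) suppressMessages(expr)
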