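# Gauss-Hermite quadrature against the standard normal density:
# integral f(t) phi(t) dt  ~=  sum w_i f(x_i).

gauss_hermite_normal <- function(n) {
  gh <- pracma::gaussHermite(n)
  list(x = sqrt(2) * gh$x, w = gh$w / sqrt(pi))
}
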