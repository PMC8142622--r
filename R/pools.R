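# Bundled sampling pools for the synthetic registry generator: Brazilian
# given names (by sex), surnames, name particles and IBGE-style 7-digit
# municipality codes. The lists are small on purpose -- enough to reproduce
# the linkage difficulties that matter (accented characters, particles,
# shared frequent surnames) without shipping national tables.

.GIVEN_F <- c(
  "Maria", "Ana", "Francisca", "Antônia", "Adriana", "Juliana", "Márcia",
  "Fernanda", "Patrícia", "Aline", "Sandra", "Camila", "Amanda", "Bruna",
  "Jéssica", "Letícia", "Júlia", "Luciana", "Vanessa", "Mariana", "Gabriela",
  "Vera", "Vitória", "Larissa", "Cláudia", "Beatriz", "Luana", "Rita",
  "Rosângela", "Conceição", "Aparecida", "Fátima", "Terezinha", "Luzia",
  "Joana", "Raimunda", "Severina", "Josefa", "Edna", "Regina", "Simone",
  "Tatiane", "Daniela", "Carla", "Renata", "Priscila", "Michele", "Elaine",
  "Cristiane", "Débora", "Sônia", "Helena", "Alice", "Laura", "Cecília",
  "Isabel", "Lúcia", "Rosa", "Iracema", "Socorro"
)

.GIVEN_M <- c(
  "José", "João", "Antônio", "Francisco", "Carlos", "Paulo", "Pedro",
  "Lucas", "Luiz", "Marcos", "Luís", "Gabriel", "Rafael", "Daniel",
  "Marcelo", "Bruno", "Eduardo", "Felipe", "Raimundo", "Rodrigo", "Manoel",
  "Mateus", "André", "Fernando", "Fábio", "Leonardo", "Gustavo", "Guilherme",
  "Leandro", "Tiago", "Sebastião", "Cícero", "Alexandre", "Márcio", "Sérgio",
  "Ricardo", "Cláudio", "Geraldo", "Adriano", "Júlio", "César", "Renato",
  "Vítor", "Jorge", "Roberto", "Edson", "Caio", "Otávio", "Heitor", "Enzo",
  "Benedito", "Valdir", "Osvaldo", "Joaquim", "Vicente", "Expedito",
  "Severino", "Domingos", "Ernesto", "Augusto"
)

.SURNAMES <- c(
  "Silva", "Santos", "Oliveira", "Souza", "Rodrigues", "Ferreira", "Alves",
  "Pereira", "Lima", "Gomes", "Costa", "Ribeiro", "Martins", "Carvalho",
  "Almeida", "Lopes", "Soares", "Fernandes", "Vieira", "Barbosa", "Rocha",
  "Dias", "Nascimento", "Andrade", "Moreira", "Nunes", "Marques", "Machado",
  "Mendes", "Freitas", "Cardoso", "Ramos", "Gonçalves", "Santana", "Teixeira",
  "Araújo", "Cavalcanti", "Correia", "Campos", "Castro", "Miranda", "Pinto",
  "Moura", "Cunha", "Monteiro", "Azevedo", "Barros", "Batista", "Duarte",
  "Farias", "Melo", "Nogueira", "Pires", "Queiroz", "Sales", "Tavares",
  "Assunção", "Brandão", "Conceição", "Espírito Santo", "Guimarães",
  "Magalhães", "Medeiros", "Moraes", "Neves", "Peixoto", "Rezende",
  "Sampaio", "Siqueira", "Xavier"
)

.PARTICLES <- c("da", "de", "do", "das", "dos", "e")

# Zipf-like sampling weights: frequent names dominate, as in real registries.
.zipf_weights <- function(n) 1 / seq_len(n)

# IBGE-style municipality codes: 2-digit state prefix + 5 further digits.
# Built deterministically; ~100 codes spanning 25 state prefixes.
.municipality_pool <- function() {
  uf <- c(11, 12, 13, 14, 15, 16, 17, 21, 22, 23, 24, 25, 26, 27, 28, 29,
          31, 32, 33, 35, 41, 42, 43, 50, 51, 52)
  known <- c("2927408", "3550308", "3304557", "2304400", "1302603",
             "5300108", "2611606", "3106200", "4106902", "2111300")
  synth <- unlist(lapply(uf, function(u) {
    sprintf("%02d%04d%d", u, c(103, 409, 712, 1508), (u * 7) %% 10)
  }))
  unique(c(known, synth))
}

#' Default sampling pools for the synthetic registry generator
#'
#' Returns the bundled pools of Brazilian-style given names (per sex),
#' surnames, name particles (DA, DE, DOS, ...) and IBGE-style 7-digit
#' municipality codes used by [generate_population()]. Supply a modified
#' copy to control the sampling universe.
#'
#' @return A named list with elements `given_f`, `given_m`, `surnames`,
#'   `particles` and `municipality_codes`. Names are sampled with Zipf-like
#'   weights (frequency rank 1/i), so frequent names dominate as they do in
#'   real registries.
#' @export
#' @examples
#' pools <- default_pools()
#' length(pools$municipality_codes)
default_pools <- function() {
  list(
    given_f = .GIVEN_F,
    given_m = .GIVEN_M,
    surnames = .SURNAMES,
    particles = .PARTICLES,
    municipality_codes = .municipality_pool()
  )
}
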