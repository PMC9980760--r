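# Infection ICD-10 codes and prefixes: a documented reconstruction seeded
# from the three chapters that dominate hospital infection coding
# (respiratory J, infectious/parasitic A-B, genitourinary N) plus common
# site-specific infection categories from the implicit-sepsis literature.
# Replace with a locally validated list where available. Explicit sepsis
# codes (A40, A41, R57.2) are kept in the separate sepsis list and are
# excluded from this one at load time.

# Certain infectious and parasitic diseases (whole chapter)
A00
A01
A02
A03
A04
A05
A06
A07
A08
A09
A15
A16
A17
A18
A19
A20
A21
A22
A23
A24
A25
A26
A27
A28
A31
A32
A33
A34
A35
A36
A37
A38
A39
A42
A43
A44
A46     # erysipelas
A48
A49
B00
B01
B02
B05
B15
B16
B17
B18
B20
B25
B26
B27
B33
B34
B37     # candidiasis
B44
B49
B50
B54
B95
B96
B97
B99

# Respiratory infections
J00
J01
J02
J03
J04
J05
J06
J09
J10
J11
J12
J13
J14
J15
J16
J17
J18     # pneumonia, organism unspecified
J20
J21
J22
J32
J36
J39.0
J39.1
J44.0   # COPD with acute lower respiratory infection
J69     # aspiration pneumonitis
J85
J86

# Genitourinary infections
N10     # acute pyelonephritis
N11
N12
N13.6
N15.1
N30     # cystitis
N34
N39.0   # urinary tract infection, site not specified
N41
N43.1
N45
N48.1
N48.2
N49
N61
N70
N71
N72
N73
N74
N75
N76

# Nervous system, circulatory, digestive, skin, bone and other sites
G00     # bacterial meningitis
G01
G02
G03
G04
G06
G07
I33     # acute and subacute endocarditis
I38
I40.0
I80
K35     # acute appendicitis
K37
K57.0
K57.2
K57.4
K57.8
K61     # abscess of anal and rectal regions
K63.0
K65     # peritonitis
K75.0
K80.0
K80.3
K81.0
K83.0
L02     # cutaneous abscess, furuncle and carbuncle
L03     # cellulitis
L04
L05.0
L08
M00     # pyogenic arthritis
M01
M46.2
M46.3
M46.5
M72.6
M86     # osteomyelitis
O85
O86
T79.3
T81.4   # infection following a procedure
T82.6
T82.7
T83.5
T83.6
T84.5
T84.6
T84.7
T85.7
R65.0   # SIRS of infectious origin without organ failure
R65.1
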