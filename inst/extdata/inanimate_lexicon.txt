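# Inanimate head nouns used by the annotation generator.
anchor
arrow
boat
bottle
bowl
bridge
building
candle
car
castle
chair
church
cup
door
flag
fountain
hammer
hat
house
kite
lamp
letter
mountain
plane
pot
ramp
rocket
roof
sail
ship
shoe
sword
table
teapot
tent
tower
tree
truck
vase
windmill
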